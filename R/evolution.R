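#' Propose a mutation to a genotype
#'
#' Mutations change initial expression by one molecule while conserving the
#' total: `x0 -> x0 + 1` or `x0 -> x0 - 1`, each with probability 1/2 (so
#' `y0 = gmax - x0` moves oppositely). Proposals stepping outside
#' `[0, gmax]` are returned flagged infeasible; they still count as sampled
#' mutational events in the evolutionary simulation.
#'
#' @param x0 current genotype.
#' @param gmax total molecule count.
#' @return list with `x0` (the proposed genotype) and `feasible` (logical).
#' @export
propose_mutation <- function(x0, gmax = 60) {
  stopifnot(x0 >= 0, x0 <= gmax)
  step <- if (stats::runif(1) < 0.5) 1L else -1L
  prop <- x0 + step
  list(x0 = prop, feasible = prop >= 0 && prop <= gmax)
}

# Fixation probability of the one-step beneficial mutation x0 -> x0 + 1,
# cached per (switch, environment, x0) since it depends only on the genotypes.
step_fixation <- function(switch, x0, env, cache = NULL) {
  p1 <- hedge_probability(switch, x0)
  p2 <- hedge_probability(switch, x0 + 1L)
  fixation_probability(p1, p2, env)$pi
}

#' Simulate the evolutionary loss of bet-hedging (SSWM)
#'
#' Strong-selection weak-mutation simulation: the population is isogenic with
#' genotype `x0`; repeatedly a mutant genotype is proposed by
#' [propose_mutation()], its fixation probability `pi` is computed from the
#' branching-process invasion model with `p1 = p(x0)` and `p2 = p(x0')`, and
#' the mutation fixes iff `q < pi` for `q ~ Unif(0, 1)`. Every sampled
#' proposal (fixed, lost or infeasible) increments the event counter. The
#' simulation terminates when `x0 = gmax` — bet-hedging is lost, all newborns
#' take phenotype A — or when `event_cap` proposals have been sampled
#' (censored; expected for the AM switch, whose late mutations are
#' effectively neutral and cannot fix in an infinite population).
#'
#' @param switch a [make_switch()] model.
#' @param x0 initial genotype (interior: `0 < x0 < gmax`), by default the
#'   genotype whose hedge probability is closest to 0.5.
#' @param env a [env_spec()] environment, fixed throughout.
#' @param seed optional integer seed.
#' @param event_cap cap on sampled mutational events (default `1e6`).
#' @return list of class `sswm_trajectory`: `records` (data.frame with one
#'   row per fixed genotype: `events` cumulative sampled events, `x0`, `p`),
#'   `loss_time` (total events at first `x0 = gmax`, `NA` if censored),
#'   `censored` flag.
#' @examples
#' dcy <- make_switch("DCy")
#' tr <- sswm_trajectory(dcy, x0 = 53, seed = 1)
#' tr$loss_time
#' @export
sswm_trajectory <- function(switch, x0 = closest_to_half(switch),
                            env = env_spec(), seed = NULL, event_cap = 1e6) {
  stopifnot(inherits(switch, "switch_model"),
            x0 > 0, x0 < switch$gmax, event_cap > 0)
  if (!is.null(seed)) set.seed(seed)
  gmax <- switch$gmax
  # pi depends only on the genotype pair, not on history: precompute the
  # beneficial-step ladder once
  pi_up <- vapply(x0:(gmax - 1L), function(g) step_fixation(switch, g, env),
                  numeric(1))
  g <- as.integer(x0)
  events <- 0
  rec_events <- 0
  rec_x0 <- g
  censored <- FALSE
  repeat {
    if (g == gmax) break
    if (events >= event_cap) { censored <- TRUE; break }
    events <- events + 1
    up <- stats::runif(1) < 0.5
    prop <- g + if (up) 1L else -1L
    if (prop < 0 || prop > gmax) next        # infeasible, still an event
    if (prop < g) next                       # deleterious: pi = 0, never fixes
    pi <- pi_up[g - x0 + 1L]
    if (pi > 0 && stats::runif(1) < pi) {
      g <- prop
      rec_events <- c(rec_events, events)
      rec_x0 <- c(rec_x0, g)
    }
  }
  out <- list(
    records = data.frame(events = rec_events, x0 = rec_x0,
                         p = hedge_probability(switch, rec_x0)),
    loss_time = if (censored) NA_real_ else events,
    censored = censored)
  class(out) <- "sswm_trajectory"
  out
}

#' @export
print.sswm_trajectory <- function(x, ...) {
  if (x$censored) {
    cat("SSWM trajectory: censored at", max(x$records$events), "events;",
        "last genotype", x$records$x0[nrow(x$records)], "\n")
  } else {
    cat("SSWM trajectory: bet-hedging lost after", x$loss_time,
        "sampled mutational events\n")
  }
  invisible(x)
}

#' Genotype with hedge probability closest to one half
#'
#' Ties are broken toward the smaller deviation `|p - 0.5|`, then the smaller
#' `x0`. For DC and AM this is `gmax / 2`; for the calibrated DCx and DCy at
#' `gmax = 60` it is `x0 = 7` (p = 0.49) and `x0 = 53` (p = 0.51).
#'
#' @param switch a `switch_model`.
#' @return integer genotype.
#' @export
closest_to_half <- function(switch) {
  x0 <- 0:switch$gmax
  p <- hedge_probability(switch, x0)
  x0[which.min(abs(p - 0.5))]
}

#' Closed-form expected time to loss of bet-hedging
#'
#' Only beneficial one-step mutations can fix, so the evolutionary loss of
#' bet-hedging is a ratchet through `x0, x0 + 1, ..., gmax`. The number of
#' sampled mutational events spent waiting at genotype `g` is geometric with
#' success probability `0.5 pi(g -> g+1)` (half of proposals are the
#' beneficial direction), so the expected loss time is the sum of
#' `1 / (0.5 pi)` over the ladder — a sum of expectations of nonidentical
#' independent geometric distributions. If any step has `pi = 0` (the AM
#' switch: late steps are effectively neutral) the expectation is infinite.
#'
#' @inheritParams sswm_trajectory
#' @return expected number of sampled mutational events (possibly `Inf`).
#' @examples
#' expected_loss_time(make_switch("DC"), 30)   # 3382.8
#' @export
expected_loss_time <- function(switch, x0 = closest_to_half(switch),
                               env = env_spec()) {
  stopifnot(inherits(switch, "switch_model"), x0 >= 0, x0 <= switch$gmax)
  gmax <- switch$gmax
  if (x0 == gmax) return(0)
  total <- 0
  for (g in x0:(gmax - 1L)) {
    pi <- step_fixation(switch, g, env)
    if (pi <= 0) return(Inf)
    total <- total + 1 / (0.5 * pi)
  }
  total
}
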