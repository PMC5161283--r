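#' Drug treatment regimes
#'
#' Per-hour death (`d`) and reproduction (`f`) probabilities for each
#' phenotype under treatment. The drug acts on the proliferative phenotype A
#' only; the persister-like phenotype B keeps its hospitable-environment
#' parameters (`dB = 0.005`, `fB = 0.015`) in every preset:
#'
#' * `cytostatic`: fully inhibits reproduction of A (`fA = 0`, `dA = 0.005`).
#' * `cytotoxic`: raises the death probability of A (`dA = 0.8`, `fA = 1.0`).
#' * `mixed`: a trade-off between the two (`dA = 0.4`, `fA = 0.5`).
#' * `hospitable`: the no-drug environment (`dA = 0.005`, `fA = 1.0`),
#'   matching offspring numbers of approximately 2 and 1.01.
#'
#' @param name preset name, or `"custom"` with all four probabilities given.
#' @param dA,fA,dB,fB per-hour probabilities overriding the preset.
#' @return object of class `drug_regime` with fields `name`, `dA`, `fA`,
#'   `dB`, `fB`.
#' @export
drug_regime <- function(name = c("cytotoxic", "cytostatic", "mixed",
                                 "hospitable", "custom"),
                        dA = NULL, fA = NULL, dB = NULL, fB = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    cytostatic = list(dA = 0.005, fA = 0.0),
    cytotoxic  = list(dA = 0.8,   fA = 1.0),
    mixed      = list(dA = 0.4,   fA = 0.5),
    hospitable = list(dA = 0.005, fA = 1.0),
    custom     = list(dA = NA,    fA = NA))
  out <- list(name = name,
              dA = if (is.null(dA)) preset$dA else dA,
              fA = if (is.null(fA)) preset$fA else fA,
              dB = if (is.null(dB)) 0.005 else dB,
              fB = if (is.null(fB)) 0.015 else fB)
  probs <- unlist(out[c("dA", "dB")])
  if (any(is.na(unlist(out[-1]))))
    stop("custom regime requires dA, fA (dB, fB default to 0.005, 0.015)")
  if (any(probs < 0) || any(probs > 1) || out$fA < 0 || out$fB < 0)
    stop("death probabilities must lie in [0, 1] and f >= 0")
  structure(out, class = "drug_regime")
}

#' @export
print.drug_regime <- function(x, ...) {
  cat(sprintf("%s regime: dA=%g fA=%g dB=%g fB=%g (wA=%g, wB=%g)\n",
              x$name, x$dA, x$fA, x$dB, x$fB,
              offspring_number(x$dA, x$fA), offspring_number(x$dB, x$fB)))
  invisible(x)
}

#' Mean fitness under treatment
#'
#' `<w_drug> = p (1 - dA)(1 + fA) + (1 - p)(1 - dB)(1 + fB)`. While this is
#' at least 1 the treated population does not decline on average and
#' extinction almost surely never occurs — useful as an early-warning
#' diagnostic before running replicates.
#'
#' @param p hedge probability of the (post-holiday) genotype.
#' @param regime a [drug_regime()].
#' @return numeric (vectorised over `p`).
#' @export
drug_mean_fitness <- function(p, regime) {
  stopifnot(inherits(regime, "drug_regime"))
  p * offspring_number(regime$dA, regime$fA) +
    (1 - p) * offspring_number(regime$dB, regime$fB)
}

#' Critical cytostatic efficacy
#'
#' A purely cytostatic drug (acting only on `fA`) can drive the sensitive
#' compartment into decline only if `(1 - dA)(1 + fA) < 1`, i.e.
#' `fA < 1 / (1 - dA) - 1`. At the background death probability `dA = 0.005`
#' the threshold is about 0.005 — the drug must suppress reproduction almost
#' completely before extinction is even possible.
#'
#' @param dA per-hour death probability of phenotype A (default 0.005).
#' @return the threshold reproduction probability.
#' @export
cytostatic_threshold <- function(dA = 0.005) {
  stopifnot(dA >= 0, dA < 1)
  1 / (1 - dA) - 1
}

#' Expected genotype after a treatment holiday
#'
#' During a drug-free holiday of `T` mutational events the population genotype
#' ratchets toward `gmax`. The expected number of sampled events for the next
#' beneficial genotype `g + 1` to arise and fix is `1 / (0.5 pi(g -> g + 1))`
#' (only half of the proposals are beneficial), so the expected post-holiday
#' genotype is found by accumulating these expectations from `g0` and
#' stopping at the last genotype whose cumulative cost does not exceed `T`.
#' If some step has `pi = 0` (AM: effectively neutral late steps) the
#' genotype freezes there for all larger `T`.
#'
#' @param switch a [make_switch()] model.
#' @param x0 genotype at the start of the holiday.
#' @param T holiday length in mutational events (non-negative).
#' @param env hospitable-environment [env_spec()] used during the holiday.
#' @return list with `x0` (post-holiday genotype), `p` (its hedge
#'   probability) and `events_used` (cumulative expected events).
#' @examples
#' dcy <- make_switch("DCy")
#' post_holiday_genotype(dcy, 53, 3000)$x0   # 60: hedge fully lost
#' @export
post_holiday_genotype <- function(switch, x0, T, env = env_spec()) {
  stopifnot(inherits(switch, "switch_model"), T >= 0,
            x0 >= 0, x0 <= switch$gmax)
  g <- as.integer(x0)
  used <- 0
  while (g < switch$gmax) {
    pi <- step_fixation(switch, g, env)
    if (pi <= 0) break
    cost <- 1 / (0.5 * pi)
    if (used + cost > T) break
    used <- used + cost
    g <- g + 1L
  }
  list(x0 = g, p = hedge_probability(switch, g), events_used = used)
}

#' Stochastic birth-death simulation of drug treatment
#'
#' Simulates an hourly death-then-birth process for a two-phenotype
#' population under treatment, without mutation. Each replicate starts from
#' `nA = round(p N0)` phenotype-A and `nB = N0 - nA` phenotype-B
#' individuals. Every hour, per phenotype `i`: survivors are
#' `Binomial(n_i, 1 - d_i)`; of these, `Binomial(survivors, f_i)` reproduce;
#' each newborn takes phenotype A with probability `p` independently (parents
#' retain their phenotype). Extinction is recorded when `nA + nB = 0`;
#' replicates still alive at `horizon` hours are censored there. All
#' replicates advance together on one RNG stream (vectorised binomial
#' compartments keep `N0 = 1e10` tractable; sizes beyond 2^31 use a normal
#' approximation).
#'
#' @param p hedge probability of the treated population's genotype.
#' @param regime a [drug_regime()].
#' @param N0 initial population size (default `1e10`).
#' @param horizon censoring time in hours (default 20000).
#' @param replicates number of replicate simulations (default 2000).
#' @param success_threshold extinction before this many hours counts as a
#'   potentially successful course of therapy (default 240, about a 10-day
#'   antibiotic course).
#' @param seed optional integer seed.
#' @return data.frame of class `treatment_outcome` with one row per
#'   replicate: `extinct`, `t_ext` (hours, censored at `horizon`),
#'   `successful` (`t_ext < success_threshold`); attribute
#'   `drug_mean_fitness`.
#' @examples
#' out <- treatment_simulation(1, drug_regime("cytotoxic"), N0 = 1e6,
#'                             replicates = 10, seed = 1)
#' summary(out$t_ext)
#' @export
treatment_simulation <- function(p, regime, N0 = 1e10, horizon = 20000,
                                 replicates = 2000, success_threshold = 240,
                                 seed = NULL) {
  stopifnot(inherits(regime, "drug_regime"), p >= 0, p <= 1, N0 >= 1,
            horizon >= success_threshold, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  nA <- rep(round(p * N0), replicates)
  nB <- rep(N0 - round(p * N0), replicates)
  t_ext <- rep(NA_real_, replicates)
  alive <- rep(TRUE, replicates)
  for (h in seq_len(horizon)) {
    idx <- which(alive)
    if (!length(idx)) break
    survA <- rbinom_large(length(idx), nA[idx], 1 - regime$dA)
    survB <- rbinom_large(length(idx), nB[idx], 1 - regime$dB)
    repro <- rbinom_large(length(idx), survA, regime$fA) +
      rbinom_large(length(idx), survB, regime$fB)
    newA <- rbinom_large(length(idx), repro, p)
    nA[idx] <- survA + newA
    nB[idx] <- survB + (repro - newA)
    dead <- idx[nA[idx] + nB[idx] == 0]
    if (length(dead)) {
      t_ext[dead] <- h
      alive[dead] <- FALSE
    }
  }
  out <- data.frame(
    replicate = seq_len(replicates),
    extinct = !alive,
    t_ext = ifelse(alive, horizon, t_ext),
    successful = !alive & !is.na(t_ext) & t_ext < success_threshold)
  attr(out, "drug_mean_fitness") <- drug_mean_fitness(p, regime)
  class(out) <- c("treatment_outcome", "data.frame")
  out
}

#' Treatment-holiday sweep
#'
#' For each holiday length `T`, computes the expected post-holiday genotype
#' and its hedge probability, runs the treatment simulation, and summarises
#' the extinction-time distribution. Conditions are classified as
#' `"no_extinction"` (no replicate extinct within the horizon),
#' `"extinct_late"` (extinction occurs but typically after
#' `success_threshold`), or `"successful"` (most replicates extinct before
#' `success_threshold`).
#'
#' @inheritParams post_holiday_genotype
#' @inheritParams treatment_simulation
#' @param T_list holiday lengths in mutational events
#'   (default `c(0, 3000, 5000, 50000, 100000)`).
#' @param seed master seed; each condition uses a derived stream so the sweep
#'   is reproducible as a whole and per condition.
#' @return data.frame with one row per holiday length: `T`, `g`, `p`,
#'   `extinct_fraction`, `success_fraction`, `min_t_ext`, `median_t_ext`
#'   (over extinct replicates), `classification`.
#' @export
holiday_sweep <- function(switch, x0 = closest_to_half(switch),
                          T_list = c(0, 3000, 5000, 50000, 100000),
                          regime = drug_regime("cytotoxic"),
                          env = env_spec(), N0 = 1e10, horizon = 20000,
                          replicates = 2000, success_threshold = 240,
                          seed = NULL) {
  rows <- lapply(seq_along(T_list), function(i) {
    T <- T_list[i]
    ph <- post_holiday_genotype(switch, x0, T, env)
    sim <- treatment_simulation(ph$p, regime, N0 = N0, horizon = horizon,
                                replicates = replicates,
                                success_threshold = success_threshold,
                                seed = if (is.null(seed)) NULL
                                       else derive_seed(seed, i))
    ext <- sim$t_ext[sim$extinct]
    ext_frac <- mean(sim$extinct)
    succ_frac <- mean(sim$successful)
    data.frame(
      T = T, g = ph$x0, p = ph$p,
      extinct_fraction = ext_frac,
      success_fraction = succ_frac,
      min_t_ext = min(sim$t_ext),
      median_t_ext = if (length(ext)) stats::median(ext) else NA_real_,
      classification = if (ext_frac == 0) "no_extinction"
                       else if (succ_frac >= 0.5) "successful"
                       else "extinct_late")
  })
  out <- do.call(rbind, rows)
  attr(out, "switch") <- switch$kind
  attr(out, "regime") <- regime$name
  out
}
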