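#' Fixation probability of a single invading mutant
#'
#' Probability that a single mutant whose genotype confers hedge probability
#' `p2` fixes in an infinite isogenic resident population with hedge
#' probability `p1`, under Wright-Fisher reproduction in a fixed environment.
#' The mutant lineage is a two-type branching process: a parent of phenotype
#' `j` leaves `Poisson(w_j / <w>)` offspring (resident mean fitness
#' `<w> = p1 wA + (1 - p1) wB` normalises the fixed population size), each
#' independently of phenotype A with probability `p2`. The phenotype-
#' conditioned survival probabilities solve the componentwise fixed point
#' \deqn{1 - \pi_j = \exp(-\sum_i M_{ij} \pi_i), \quad M_{ij} = w_j q_i /
#' \langle w\rangle,} with `q = (p2, 1 - p2)`. Because every column of `M` is
#' proportional to `q`, the system collapses to a scalar equation for the
#' genotype-level probability `S = p2 pi_A + (1 - p2) pi_B`:
#' `S = p2 (1 - exp(-wA S / <w>)) + (1 - p2)(1 - exp(-wB S / <w>))`, whose
#' maximal root is found by Newton iteration from `S = 1` (monotone for this
#' concave map, and quadratically convergent even near criticality, where
#' plain fixed-point iteration from `(1, 1)` stalls). When the invader's
#' growth factor `lambda' = (p2 wA + (1 - p2) wB) / <w>` is at most 1 the
#' process is (sub)critical and `pi = 0` exactly: deleterious and neutral
#' mutations cannot fix.
#'
#' @param p1 resident hedge probability.
#' @param p2 invader hedge probability.
#' @param env a [env_spec()] environment.
#' @param tol absolute sup-norm convergence tolerance on the fixation
#'   probability (default `1e-12`); probabilities this small are
#'   indistinguishable from criticality and effectively zero.
#' @param max_iter iteration cap (default `1e5`).
#' @return list of class `invasion_result`: `pi_A`, `pi_B` (phenotype-
#'   conditioned), `pi` (genotype-level), `supercritical`, `growth_factor`.
#' @examples
#' fixation_probability(0.5, 31 / 60)$pi
#' fixation_probability(0.5, 0.4)$pi    # 0: deleterious
#' @export
fixation_probability <- function(p1, p2, env = env_spec(),
                                 tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(env, "hedge_env"),
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  wbar <- mean_fitness(p1, env)
  lambda <- mean_fitness(p2, env) / wbar
  if (lambda <= 1) {
    res <- list(pi_A = 0, pi_B = 0, pi = 0,
                supercritical = FALSE, growth_factor = lambda)
    class(res) <- "invasion_result"
    return(res)
  }
  a <- env$wA / wbar
  b <- env$wB / wbar
  g <- function(S) p2 * (1 - exp(-a * S)) + (1 - p2) * (1 - exp(-b * S)) - S
  gprime <- function(S) p2 * a * exp(-a * S) + (1 - p2) * b * exp(-b * S) - 1
  S <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- g(S) / gprime(S)
    S_new <- S - step
    if (S_new <= 0 || S_new > 1) S_new <- S / 2   # safeguard, rarely taken
    if (abs(S_new - S) < tol || abs(g(S_new)) < 1e-17) {
      S <- S_new; converged <- TRUE; break
    }
    S <- S_new
  }
  if (!converged)
    stop(sprintf(paste0("Newton iteration did not converge in %d ",
                        "iterations (last iterate: S=%.3e, residual=%.3e)"),
                 max_iter, S, g(S)))
  res <- list(pi_A = 1 - exp(-a * S), pi_B = 1 - exp(-b * S), pi = S,
              supercritical = TRUE, growth_factor = lambda)
  class(res) <- "invasion_result"
  res
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("fixation probability pi = %.6g (pi_A = %.6g, pi_B = %.6g; %s)\n",
              x$pi, x$pi_A, x$pi_B,
              if (x$supercritical) "supercritical" else "subcritical"))
  invisible(x)
}

#' Grid of invasion probabilities
#'
#' Genotype-level fixation probabilities for every resident / invader hedge
#' pair on a grid, the numerical counterpart of an invasion heatmap: zero at
#' and above the antidiagonal `p2 <= p1` (for `wA > wB`), increasing toward
#' the `p2 = 1`, `p1 = 0` corner.
#'
#' @param p1 vector of resident hedge probabilities.
#' @param p2 vector of invader hedge probabilities.
#' @param env a [env_spec()] environment.
#' @return data.frame with columns `p1`, `p2`, `pi`.
#' @export
invasion_grid <- function(p1 = seq(0, 1, by = 0.02),
                          p2 = seq(0, 1, by = 0.02),
                          env = env_spec()) {
  grid <- expand.grid(p1 = p1, p2 = p2)
  grid$pi <- mapply(function(a, b) fixation_probability(a, b, env)$pi,
                    grid$p1, grid$p2)
  grid
}
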