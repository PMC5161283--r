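#' Environment: per-phenotype offspring numbers
#'
#' Describes a (fixed) environment by the expected number of offspring per
#' 60-minute timestep contributed by one individual of each phenotype, `wA`
#' and `wB` (the individual itself counts, so a cell that always survives and
#' always divides has w = 2). Alternatively the environment can be specified
#' by per-step death probabilities `dA`, `dB` and reproduction probabilities
#' of survivors `fA`, `fB`, from which `w_i = (1 - d_i)(1 + f_i)`; mixing the
#' two forms is rejected. The defaults `wA = 2.0, wB = 1.01` describe a
#' hospitable environment in which phenotype A divides about once per hour
#' and the persister-like phenotype B about 100 times more slowly.
#'
#' @param wA,wB expected offspring numbers (positive reals).
#' @param dA,fA,dB,fB optional death / reproduction probabilities; if any is
#'   given, all four must be, and `wA`/`wB` must not be.
#' @return object of class `hedge_env` with fields `wA`, `wB` and, when
#'   derived, the generating `d` and `f` values.
#' @examples
#' env_spec()                          # hospitable default
#' env_spec(dA = 0.005, fA = 1.0, dB = 0.005, fB = 0.015)
#' @export
env_spec <- function(wA = 2.0, wB = 1.01,
                     dA = NULL, fA = NULL, dB = NULL, fB = NULL) {
  df_given <- !vapply(list(dA, fA, dB, fB), is.null, logical(1))
  if (any(df_given)) {
    if (!all(df_given))
      stop("specify all of dA, fA, dB, fB or none")
    if (!missing(wA) || !missing(wB))
      stop("specify either (wA, wB) or (dA, fA, dB, fB), not both")
    wA <- offspring_number(dA, fA)
    wB <- offspring_number(dB, fB)
    out <- list(wA = wA, wB = wB, dA = dA, fA = fA, dB = dB, fB = fB)
  } else {
    out <- list(wA = wA, wB = wB)
  }
  if (out$wA <= 0 || out$wB <= 0) stop("offspring numbers must be positive")
  structure(out, class = "hedge_env")
}

#' @export
print.hedge_env <- function(x, ...) {
  cat(sprintf("environment: wA = %g, wB = %g", x$wA, x$wB))
  if (!is.null(x$dA))
    cat(sprintf(" (from dA=%g fA=%g dB=%g fB=%g)", x$dA, x$fA, x$dB, x$fB))
  cat("\n")
  invisible(x)
}

#' Offspring number from death and reproduction probabilities
#'
#' An individual that dies with probability `d` over the timestep, and if it
#' survives reproduces with probability `f`, contributes on average
#' `w = (1 - d)(1 + f)` individuals to the next timestep. Different `(d, f)`
#' pairs with the same product give identical population and invasion
#' dynamics.
#'
#' @param d per-step death probability in `[0, 1]`.
#' @param f per-step reproduction probability of survivors (non-negative).
#' @return expected offspring number (vectorised).
#' @examples
#' offspring_number(0.005, 1.0)    # 1.99, approximately 2
#' offspring_number(0.005, 0.015)  # 1.009925, approximately 1.01
#' @export
offspring_number <- function(d, f) {
  stopifnot(all(d >= 0), all(d <= 1), all(f >= 0))
  (1 - d) * (1 + f)
}

#' Mean fitness of a hedging population
#'
#' With a fraction `p` of phenotype A at equilibrium, the average number of
#' descendants per individual per timestep is `<w> = p wA + (1 - p) wB`.
#'
#' @param p probability of phenotype A at birth.
#' @param env a [env_spec()] environment.
#' @return numeric mean fitness (vectorised over `p`).
#' @export
mean_fitness <- function(p, env = env_spec()) {
  stopifnot(inherits(env, "hedge_env"), all(p >= 0), all(p <= 1))
  p * env$wA + (1 - p) * env$wB
}

#' Projection matrix of the two-phenotype population
#'
#' The quasispecies-style projection matrix governing the phenotype
#' composition `x(t+1) = P x(t)` of a population whose newborns take
#' phenotype A with probability `p`, normalised by the mean fitness so that
#' the dominant eigenvalue is exactly 1:
#' \deqn{P = \frac{1}{\langle w\rangle}
#'   \begin{pmatrix} w_A p & w_B p \\ w_A (1-p) & w_B (1-p)\end{pmatrix}.}
#'
#' @inheritParams mean_fitness
#' @return 2x2 matrix with `dimnames` `A`/`B`, with attribute `mean_fitness`.
#' @export
projection_matrix <- function(p, env = env_spec()) {
  stopifnot(length(p) == 1, p >= 0, p <= 1)
  wbar <- mean_fitness(p, env)
  P <- matrix(c(env$wA * p, env$wA * (1 - p),
                env$wB * p, env$wB * (1 - p)) / wbar,
              nrow = 2, dimnames = list(c("A", "B"), c("A", "B")))
  attr(P, "mean_fitness") <- wbar
  P
}

#' Stationary phenotype distribution
#'
#' The long-term fractions of phenotypes A and B are `(p, 1 - p)`: the
#' normalised dominant eigenvector of the projection matrix, whose dominant
#' eigenvalue under the mean-fitness normalisation is 1. The eigenpair
#' identity `P (p, 1-p)' = (p, 1-p)'` is verified numerically on return.
#'
#' @inheritParams mean_fitness
#' @return named numeric vector `c(A = p, B = 1 - p)`.
#' @examples
#' stationary_distribution(0.3)  # c(A = 0.3, B = 0.7)
#' @export
stationary_distribution <- function(p, env = env_spec()) {
  stopifnot(length(p) == 1, p >= 0, p <= 1)
  v <- c(A = p, B = 1 - p)
  P <- projection_matrix(p, env)
  if (max(abs(P %*% v - v)) > 1e-10)
    stop("internal error: (p, 1-p) failed the eigenvector identity")
  v
}
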