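# Independent oracles used across the suite. Each one recomputes a quantity
# by brute force (dense linear algebra, direct enumeration, or naive
# simulation) without going through the package's solvers.

# Absorption probability at x = total for the birth-death walk with constant
# up-step probability p_up, by dense linear solve of the harmonic system.
oracle_walk_absorption <- function(total, p_up = 0.5) {
  n <- total - 1                       # interior states 1..total-1
  A <- diag(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    if (i < n) A[i, i + 1] <- -p_up else b[i] <- p_up       # hits total
    if (i > 1) A[i, i - 1] <- -(1 - p_up)
  }
  h <- solve(A, b)
  c(0, h, 1)                           # indexed by x0 = 0..total
}

# Stationary phenotype composition by power iteration of the projection
# matrix from a pure-A start.
oracle_power_iteration <- function(p, env, tol = 1e-12) {
  P <- hedgesim::projection_matrix(p, env)
  v <- c(1, 0)
  for (i in 1:10000) {
    v_new <- as.numeric(P %*% v)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# Survival frequency of a two-type branching lineage by direct Monte-Carlo:
# Poisson offspring with parent-type mean w_j / <w>, each newborn type A with
# probability p2. A lineage counts as surviving once it exceeds `escape`
# individuals or is still alive after `gens` generations.
oracle_branching_mc <- function(p1, p2, env, n_lineages = 1e5,
                                gens = 2000, escape = 1000) {
  wbar <- p1 * env$wA + (1 - p1) * env$wB
  nA <- stats::rbinom(n_lineages, 1, p2)
  nB <- 1L - nA
  survived <- 0L
  active <- rep(TRUE, n_lineages)
  for (g in seq_len(gens)) {
    idx <- which(active)
    if (!length(idx)) break
    mean_off <- (nA[idx] * env$wA + nB[idx] * env$wB) / wbar
    newA <- stats::rpois(length(idx), mean_off * p2)
    newB <- stats::rpois(length(idx), mean_off * (1 - p2))
    nA[idx] <- newA
    nB[idx] <- newB
    tot <- newA + newB
    esc <- idx[tot >= escape]
    survived <- survived + length(esc)
    active[esc] <- FALSE
    active[idx[tot == 0]] <- FALSE
  }
  (survived + sum(active)) / n_lineages
}

# Hourly death-then-birth treatment process simulated individual by
# individual (Bernoulli draws per cell), for small populations.
oracle_individual_treatment <- function(p, regime, N0, horizon) {
  is_A <- stats::runif(N0) < p
  for (h in seq_len(horizon)) {
    n <- length(is_A)
    if (n == 0) return(h - 1)          # extinct at the end of previous hour
    d <- ifelse(is_A, regime$dA, regime$dB)
    is_A <- is_A[stats::runif(n) > d]
    n <- length(is_A)
    if (n == 0) return(h)
    f <- ifelse(is_A, regime$fA, regime$fB)
    parents <- stats::runif(n) < f
    newborn_A <- stats::runif(sum(parents)) < p
    is_A <- c(is_A, newborn_A)
  }
  NA_real_                             # censored
}

# Shared fixtures
default_env <- hedgesim::env_spec()
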