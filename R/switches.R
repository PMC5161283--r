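#' @useDynLib hedgesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.hedgesim_cache <- new.env(parent = emptyenv())

#' Genotypes as initial molecule counts
#'
#' A genotype is the heritable initial condition of the molecular switch: the
#' number `x0` of `x` molecules present at birth, with `y0 = gmax - x0` so
#' that total initial expression is conserved (three-species switches start
#' with `b0 = 0`).
#'
#' @param x0 integer in `[0, gmax]`.
#' @param gmax total initial molecule count (default 60).
#' @return object of class `genotype` with fields `x0`, `y0`, `gmax`.
#' @export
genotype <- function(x0, gmax = 60) {
  x0 <- as.integer(x0); gmax <- as.integer(gmax)
  stopifnot(length(x0) == 1, length(gmax) == 1, gmax >= 1)
  if (x0 < 0 || x0 > gmax) stop("x0 must lie in [0, gmax]")
  structure(list(x0 = x0, y0 = gmax - x0, gmax = gmax), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("genotype x0 = %d, y0 = %d (gmax = %d)\n", x$x0, x$y0, x$gmax))
  invisible(x)
}

#' Calibrated rate asymmetry for the biased switches
#'
#' The biased direct-competition switches DCx and DCy multiply one
#' autocatalytic rate by a factor `bias > 1`. The package defines the
#' canonical bias by a calibration condition on the most even hedge the
#' biased switch can express at `gmax = 60`: the genotype nearest a 0.5 hedge
#' is `x0 = 7` for DCx with probability exactly 0.49 (equivalently, `x0 = 53`
#' for DCy with probability exactly 0.51 — the same bias satisfies both, by
#' symmetry). Solving the gambler's-ruin equation gives `bias = 1.1004881`,
#' i.e. roughly a 10% kinetic asymmetry.
#'
#' @param p_target hedge probability defining the calibration (default 0.49).
#' @param x0 genotype at which the target is imposed (default 7).
#' @param gmax total molecule count (default 60).
#' @return the bias (ratio of the favoured to the unfavoured autocatalytic
#'   rate) as a numeric scalar.
#' @export
calibrated_bias <- function(p_target = 0.49, x0 = 7, gmax = 60) {
  key <- sprintf("bias_%g_%d_%d", p_target, x0, gmax)
  if (!is.null(.hedgesim_cache[[key]])) return(.hedgesim_cache[[key]])
  f <- function(b) gamblers_ruin_probability(x0, gmax, 1 / b) - p_target
  bias <- stats::uniroot(f, c(1 + 1e-8, 2), tol = 1e-14)$root
  .hedgesim_cache[[key]] <- bias
  bias
}

#' Construct a canonical molecular switch
#'
#' Builds one of the library bistable switches as a CRN plus the metadata
#' needed to map genotypes to initial states and to compute switching
#' probabilities exactly:
#'
#' * `DC` (direct competition): `x + y -> 2x` and `x + y -> 2y`, both at rate
#'   1. The all-`x` state is phenotype A, the all-`y` state phenotype B.
#' * `DCx` / `DCy`: DC with the `x`- (respectively `y`-) autocatalytic rate
#'   multiplied by `bias` (> 1 favours the corresponding phenotype).
#' * `AM` (approximate majority): two catalytic and two autocatalytic
#'   reactions over `x`, `y` and the intermediate `b`
#'   (`x + y -> x + b`, `x + y -> y + b`, `x + b -> 2x`, `y + b -> 2y`),
#'   all at rate 1; genotypes start with `b0 = 0`.
#' * `DCdup`: DC with both species duplicated (`x, xp, y, yp`); for every
#'   pairing of an x-type with a y-type species both competitive
#'   autocatalytic reactions are present at rate 1 (8 reactions). Stable when
#'   `x + xp = 0` or `y + yp = 0`.
#'
#' @param kind one of `"DC"`, `"DCx"`, `"DCy"`, `"AM"`, `"DCdup"`.
#' @param gmax total initial molecule count of a genotype (default 60).
#' @param bias rate asymmetry for DCx/DCy (ignored otherwise); defaults to
#'   [calibrated_bias()].
#' @return object of class `switch_model`: list with `kind`, `gmax`, `bias`,
#'   `crn`, `species_class` (maps each species to `"x"`, `"y"` or `"b"`), and
#'   `embed(x0)` returning the initial [crn] state for a genotype.
#' @examples
#' am <- make_switch("AM")
#' length(am$crn$rates)         # 4 reactions
#' hedge_probability(am, 30)    # 0.5 by symmetry
#' @export
make_switch <- function(kind = c("DC", "DCx", "DCy", "AM", "DCdup"),
                        gmax = 60, bias = calibrated_bias()) {
  kind <- match.arg(kind)
  stopifnot(gmax >= 1, bias > 0)
  if (kind %in% c("DC", "AM", "DCdup")) bias <- 1

  def <- switch(kind,
    DC = list(
      reactions = c("x + y -> x + x @ 1", "x + y -> y + y @ 1"),
      absorbing = list(A = "y", B = "x"),
      class = c(x = "x", y = "y")),
    DCx = list(
      reactions = c(sprintf("x + y -> x + x @ %.17g", bias),
                    "x + y -> y + y @ 1"),
      absorbing = list(A = "y", B = "x"),
      class = c(x = "x", y = "y")),
    DCy = list(
      reactions = c("x + y -> x + x @ 1",
                    sprintf("x + y -> y + y @ %.17g", bias)),
      absorbing = list(A = "y", B = "x"),
      class = c(x = "x", y = "y")),
    AM = list(
      reactions = c("x + y -> x + b @ 1", "x + y -> y + b @ 1",
                    "x + b -> x + x @ 1", "y + b -> y + y @ 1"),
      absorbing = list(A = c("y", "b"), B = c("x", "b")),
      class = c(x = "x", y = "y", b = "b")),
    DCdup = list(
      reactions = as.vector(t(outer(
        c("x", "xp"), c("y", "yp"),
        function(a, c) paste0(a, " + ", c, " -> ", a, " + ", a, " @ 1")))),
      absorbing = list(A = c("y", "yp"), B = c("x", "xp")),
      class = c(x = "x", xp = "x", y = "y", yp = "y")))
  if (kind == "DCdup") {
    # add the symmetric y-favouring partner of each competitive pairing
    extra <- as.vector(t(outer(
      c("x", "xp"), c("y", "yp"),
      function(a, c) paste0(a, " + ", c, " -> ", c, " + ", c, " @ 1"))))
    def$reactions <- c(def$reactions, extra)
  }

  net <- crn(def$reactions, absorbing = def$absorbing,
             species = names(def$class))
  embed <- switch(kind,
    AM = function(x0) c(x = x0, y = gmax - x0, b = 0),
    DCdup = function(x0) c(x = x0, xp = 0, y = gmax - x0, yp = 0),
    function(x0) c(x = x0, y = gmax - x0))
  structure(
    list(kind = kind, gmax = as.integer(gmax), bias = bias, crn = net,
         species_class = def$class, embed = embed),
    class = "switch_model")
}

#' @export
print.switch_model <- function(x, ...) {
  cat(sprintf("%s switch (gmax = %d%s): %d species, %d reactions\n",
              x$kind, x$gmax,
              if (x$bias != 1) sprintf(", bias = %.7f", x$bias) else "",
              length(x$crn$species), length(x$crn$rates)))
  invisible(x)
}

#' Gambler's-ruin absorption probability
#'
#' Closed-form hitting probability of the upper boundary for the birth-death
#' walk underlying the direct-competition switches. Starting from `x0` of
#' `total` molecules, with `r` the ratio of the `y`- to the `x`-autocatalytic
#' rate, the probability of absorbing at `x = total` (phenotype A) is
#' `x0 / total` when `r = 1` and `(1 - r^x0) / (1 - r^total)` otherwise.
#'
#' @param x0 starting count(s) of `x` (vectorised).
#' @param total conserved total molecule count.
#' @param r ratio of y- to x-autocatalysis rates (r < 1 favours A).
#' @return probability (vector) in `[0, 1]`.
#' @examples
#' gamblers_ruin_probability(30, 60, 1)   # 0.5
#' @export
gamblers_ruin_probability <- function(x0, total, r = 1) {
  stopifnot(total >= 1, r > 0, all(x0 >= 0), all(x0 <= total))
  if (abs(r - 1) < 1e-12) return(x0 / total)
  p <- (1 - r^x0) / (1 - r^total)
  p[x0 == 0] <- 0
  p[x0 == total] <- 1
  pmin(pmax(p, 0), 1)
}

# Enumerate reachable states of a conservative CRN from `initial` and solve
# the jump-chain absorption problem into predicate-A states. Returns the
# solved probability for every enumerated state (named by state key) plus the
# key of the initial state.
solve_absorption <- function(net, initial) {
  stopifnot(inherits(net, "crn"))
  if (!is_conservative(net))
    stop("unsupported network: reactions do not conserve the molecule total")
  initial <- as_state(net, initial)
  n_sp <- length(net$species)
  a_idx <- match(net$absorbing$A, net$species)
  b_idx <- match(net$absorbing$B, net$species)
  key <- function(s) paste(s, collapse = ",")

  index <- new.env(parent = emptyenv())
  states <- list()
  kind <- integer(0)            # 0 transient, 1 absorbing-A, 2 absorbing-B/other
  queue <- list(unname(initial))
  assign(key(initial), 1L, envir = index)
  states[[1]] <- unname(initial)
  n <- 1L
  trans_i <- integer(0); trans_j <- integer(0); trans_p <- numeric(0)

  head <- 1L
  while (head <= length(queue)) {
    s <- queue[[head]]; head <- head + 1L
    i <- get(key(s), envir = index)
    if (all(s[a_idx] == 0L)) { kind[i] <- 1L; next }
    if (all(s[b_idx] == 0L)) { kind[i] <- 2L; next }
    a <- numeric(length(net$rates))
    for (r in seq_along(net$rates)) {
      val <- net$rates[r]
      for (sp in seq_len(n_sp)) {
        c_s <- net$reactant_mat[r, sp]
        if (c_s > 0) val <- val * prod(s[sp] - seq_len(c_s) + 1)
      }
      a[r] <- max(val, 0)
    }
    tot <- sum(a)
    if (tot <= 0) { kind[i] <- 2L; next }   # deadlock: never reaches A
    for (r in which(a > 0)) {
      ns <- s + net$net_mat[r, ]
      k <- key(ns)
      j <- index[[k]]
      if (is.null(j)) {
        n <- n + 1L; j <- n
        assign(k, j, envir = index)
        states[[j]] <- ns
        queue[[length(queue) + 1L]] <- ns
        kind[j] <- 0L
      }
      trans_i <- c(trans_i, i); trans_j <- c(trans_j, j)
      trans_p <- c(trans_p, a[r] / tot)
    }
    kind[i] <- 0L
  }

  h <- numeric(n)
  h[kind == 1L] <- 1
  tr <- which(kind == 0L)
  if (length(tr)) {
    pos <- integer(n); pos[tr] <- seq_along(tr)
    keep <- kind[trans_i] == 0L
    ti <- trans_i[keep]; tj <- trans_j[keep]; tp <- trans_p[keep]
    into_tr <- kind[tj] == 0L
    Q <- Matrix::sparseMatrix(i = pos[ti[into_tr]], j = pos[tj[into_tr]],
                              x = tp[into_tr],
                              dims = c(length(tr), length(tr)))
    bA <- numeric(length(tr))
    into_a <- kind[tj] == 1L
    if (any(into_a)) {
      agg <- tapply(tp[into_a], pos[ti[into_a]], sum)
      bA[as.integer(names(agg))] <- agg
    }
    sol <- Matrix::solve(Matrix::Diagonal(length(tr)) - Q, bA)
    h[tr] <- as.numeric(sol)
  }
  names(h) <- vapply(states, key, character(1))
  list(h = h, initial_key = key(initial))
}

#' Exact switching probability by Markov-chain absorption
#'
#' Enumerates the reachable configurations of a conservative CRN from the
#' given initial state, builds the embedded jump-chain transition matrix, and
#' solves the sparse linear system for the probability of absorbing into the
#' phenotype-A configuration. Exact up to linear-solver tolerance; for
#' two-species competition switches it agrees with
#' [gamblers_ruin_probability()].
#'
#' @param x a `switch_model` or a `crn`.
#' @param initial initial state (named counts), e.g. `c(x = 30, y = 30, b = 0)`.
#' @return probability of phenotype A, a numeric scalar.
#' @examples
#' am <- make_switch("AM", gmax = 10)
#' absorption_probability(am, c(x = 5, y = 5, b = 0))  # 0.5 by symmetry
#' @export
absorption_probability <- function(x, initial) {
  net <- if (inherits(x, "switch_model")) x$crn else x
  sol <- solve_absorption(net, initial)
  unname(sol$h[sol$initial_key])
}

# Absorption probabilities of the AM switch for every simplex state at a given
# gmax (solved once, cached). Returns named vector keyed "x,y,b".
am_hedge_table <- function(gmax, bias = 1) {
  key <- sprintf("am_%d", gmax)
  tab <- .hedgesim_cache[[key]]
  if (!is.null(tab)) return(tab)
  am <- make_switch("AM", gmax = gmax)
  # solve from a central interior state; the reachable set covers the simplex
  sol <- solve_absorption(am$crn, am$embed(floor(gmax / 2)))
  h <- sol$h
  # some boundary genotypes may be unreachable from the centre; solve those too
  for (x0 in 0:gmax) {
    k <- paste(c(x0, gmax - x0, 0), collapse = ",")
    if (!k %in% names(h)) {
      extra <- solve_absorption(am$crn, c(x = x0, y = gmax - x0, b = 0))
      h <- c(h, extra$h[setdiff(names(extra$h), names(h))])
    }
  }
  .hedgesim_cache[[key]] <- h
  h
}

#' Switching probability for an arbitrary initial state
#'
#' Dispatches on the switch kind: gambler's-ruin closed form for the
#' direct-competition family, the summed-count closed form for DCdup (whose
#' switching probability equals that of DC on `x + xp` of the total), and the
#' cached Markov-chain absorption solve for AM.
#'
#' @param switch a `switch_model`.
#' @param counts named vector of initial molecule counts for the switch
#'   species.
#' @return probability of phenotype A.
#' @export
switch_probability <- function(switch, counts) {
  stopifnot(inherits(switch, "switch_model"))
  counts <- as_state(switch$crn, counts)
  total <- sum(counts)
  if (total == 0) stop("initial state must contain at least one molecule")
  cls <- switch$species_class[names(counts)]
  nx <- sum(counts[cls == "x"])
  ny <- sum(counts[cls == "y"])
  if (switch$kind %in% c("DC", "DCx", "DCy")) {
    r <- rate_ratio(switch)
    gamblers_ruin_probability(nx, nx + ny, r)
  } else if (switch$kind == "DCdup") {
    nx / (nx + ny)
  } else { # AM
    tab <- am_hedge_table(total)
    k <- paste(unname(counts), collapse = ",")
    p <- tab[k]
    if (is.na(p)) p <- absorption_probability(switch$crn, counts)
    unname(p)
  }
}

# ratio of y- to x-autocatalysis rates used by the closed forms
rate_ratio <- function(switch) {
  switch(switch$kind,
         DCx = 1 / switch$bias,
         DCy = switch$bias,
         1)
}

#' Hedge probability of a genotype
#'
#' The probability `p(g)` that an individual born with genotype `x0` (that is,
#' initial state `x = x0`, `y = gmax - x0`, `b = 0` where applicable) develops
#' phenotype A. Uses the gambler's-ruin closed form for the DC family and
#' DCdup, and the exact Markov-chain absorption solve for AM. Deterministic
#' given the switch and genotype.
#'
#' @param switch a `switch_model`.
#' @param x0 genotype(s): initial `x` count, vectorised; or a [genotype()].
#' @return numeric vector of probabilities.
#' @examples
#' dc <- make_switch("DC")
#' hedge_probability(dc, 30)  # 0.5
#' @export
hedge_probability <- function(switch, x0) {
  stopifnot(inherits(switch, "switch_model"))
  if (inherits(x0, "genotype")) {
    stopifnot(x0$gmax == switch$gmax)
    x0 <- x0$x0
  }
  stopifnot(all(x0 >= 0), all(x0 <= switch$gmax))
  gmax <- switch$gmax
  if (switch$kind %in% c("DC", "DCx", "DCy", "DCdup")) {
    gamblers_ruin_probability(x0, gmax, rate_ratio(switch))
  } else {
    tab <- am_hedge_table(gmax)
    keys <- paste(x0, gmax - x0, 0, sep = ",")
    unname(tab[keys])
  }
}

#' Delete species from a switch
#'
#' Removes the named species and every reaction involving them, restricting
#' the absorbing predicates to the remaining species. Models gene deletion or
#' downregulation: the induced network keeps switching stochastically (the
#' hedge survives) but the switching probability shifts because the deleted
#' molecules no longer count.
#'
#' @param switch a `switch_model` (typically DCdup).
#' @param names character vector of species to delete.
#' @return a new `switch_model` on the remaining species.
#' @examples
#' dup <- make_switch("DCdup")
#' red <- delete_species(dup, "x")
#' switch_probability(red, c(xp = 30, y = 30, yp = 20))  # 30 / 80
#' @export
delete_species <- function(switch, names) {
  stopifnot(inherits(switch, "switch_model"))
  if (length(names) == 0) return(switch)
  bad <- setdiff(names, switch$crn$species)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  keep <- setdiff(switch$crn$species, names)
  cls <- switch$species_class[keep]
  if (!any(cls == "x") || !any(cls == "y"))
    stop("degenerate network: deletion removes all x-type or all y-type species")
  touches <- rowSums(switch$crn$reactant_mat[, names, drop = FALSE] +
                     switch$crn$product_mat[, names, drop = FALSE]) > 0
  if (all(touches)) stop("degenerate network: no reactions remain")
  new_crn <- crn(switch$crn$reaction_strings[!touches],
                 absorbing = lapply(switch$crn$absorbing, intersect, keep),
                 species = keep)
  out <- switch
  out$crn <- new_crn
  out$species_class <- cls
  out$embed <- NULL   # genotype embedding is undefined after deletion
  out
}

#' Full hedge-probability table of a switch
#'
#' @param switch a `switch_model`.
#' @return data.frame with columns `x0`, `y0`, `p` for `x0 = 0 .. gmax`.
#' @export
switch_prob_table <- function(switch) {
  x0 <- 0:switch$gmax
  data.frame(x0 = x0, y0 = switch$gmax - x0,
             p = hedge_probability(switch, x0))
}

#' Hedge-probability grid over initial conditions
#'
#' Switching probability for every initial condition `(x0, y0)` with
#' `0 < x0, y0 <= n` (and `b0 = 0` for AM), the grid underlying the contour
#' view of a switch's genotype-phenotype map.
#'
#' @param switch a `switch_model`.
#' @param n grid bound (default `switch$gmax`).
#' @return data.frame with columns `x0`, `y0`, `p`.
#' @export
switch_prob_grid <- function(switch, n = switch$gmax) {
  grid <- expand.grid(x0 = 1:n, y0 = 1:n)
  if (switch$kind == "AM") {
    grid$p <- vapply(seq_len(nrow(grid)), function(i) {
      tab <- am_hedge_table(grid$x0[i] + grid$y0[i])
      unname(tab[paste(grid$x0[i], grid$y0[i], 0, sep = ",")])
    }, numeric(1))
  } else {
    r <- rate_ratio(switch)
    grid$p <- mapply(function(a, b) gamblers_ruin_probability(a, a + b, r),
                     grid$x0, grid$y0)
  }
  grid
}
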