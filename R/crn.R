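#' Chemical reaction networks with absorbing states
#'
#' A `crn` object holds a list of chemical species and a set of mass-action
#' reactions with rates, together with two named absorbing predicates that
#' identify the stable configurations of a bistable switch. Reactions are
#' written in a plain text dialect, e.g. `"x + y -> x + x @ 1.0"`; a numeric
#' prefix such as `"2x"` is shorthand for a repeated species. Each absorbing
#' predicate is given as the set of species whose counts must all be zero for
#' the predicate to hold (for the direct-competition switch the all-`x` state
#' is simply `y == 0`).
#'
#' @param reactions character vector of reaction strings
#'   (`"reactants -> products @ rate"`).
#' @param absorbing named list with elements `A` and `B`, each a character
#'   vector of species whose counts must be zero in that stable configuration.
#' @param species optional character vector fixing the species ordering;
#'   defaults to order of first appearance in `reactions`.
#'
#' @return an object of class `crn` with components `species`, `reactant_mat`,
#'   `product_mat`, `net_mat` (reaction-by-species count matrices), `rates`,
#'   `reaction_strings` and `absorbing`.
#' @examples
#' dc <- crn(c("x + y -> x + x @ 1", "x + y -> y + y @ 1"),
#'           absorbing = list(A = "y", B = "x"))
#' propensities(dc, c(x = 30, y = 30))
#' @export
crn <- function(reactions, absorbing, species = NULL) {
  stopifnot(is.character(reactions), length(reactions) >= 1)
  parsed <- lapply(reactions, parse_reaction)
  seen <- unique(unlist(lapply(parsed, function(p) c(p$reactants, p$products))))
  if (is.null(species)) species <- seen
  if (anyDuplicated(species))
    stop("species names must be unique within a CRN")
  unknown <- setdiff(seen, species)
  if (length(unknown))
    stop("reaction uses species not in the species list: ",
         paste(unknown, collapse = ", "))

  count_mat <- function(side) {
    m <- matrix(0L, nrow = length(parsed), ncol = length(species),
                dimnames = list(NULL, species))
    for (i in seq_along(parsed)) {
      tab <- table(parsed[[i]][[side]])
      m[i, names(tab)] <- as.integer(tab)
    }
    m
  }
  reactant_mat <- count_mat("reactants")
  product_mat <- count_mat("products")
  rates <- vapply(parsed, function(p) p$rate, numeric(1))
  if (any(rates <= 0)) stop("reaction rates must be positive")

  if (!is.list(absorbing) || !all(c("A", "B") %in% names(absorbing)))
    stop("'absorbing' must be a named list with elements A and B")
  absorbing <- lapply(absorbing[c("A", "B")], as.character)
  bad <- setdiff(unlist(absorbing), species)
  if (length(bad))
    stop("absorbing predicate names unknown species: ",
         paste(bad, collapse = ", "))

  structure(
    list(species = species,
         reactant_mat = reactant_mat,
         product_mat = product_mat,
         net_mat = product_mat - reactant_mat,
         rates = rates,
         reaction_strings = reactions,
         absorbing = absorbing),
    class = "crn")
}

#' Parse one reaction string
#'
#' Accepts `"x + y -> x + x @ 1.0"`; species are listed as a multiset (with
#' optional numeric prefixes, `"2x"`), the rate follows `@` and defaults to 1.
#'
#' @param string a single reaction string.
#' @return list with `reactants` and `products` (character multisets) and
#'   `rate`.
#' @export
parse_reaction <- function(string) {
  stopifnot(is.character(string), length(string) == 1)
  rate <- 1
  main <- string
  if (grepl("@", string, fixed = TRUE)) {
    bits <- strsplit(string, "@", fixed = TRUE)[[1]]
    if (length(bits) != 2) stop("malformed reaction (expect one '@'): ", string)
    main <- bits[1]
    rate <- suppressWarnings(as.numeric(trimws(bits[2])))
    if (is.na(rate)) stop("malformed rate in reaction: ", string)
  }
  sides <- strsplit(main, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("malformed reaction (expect one '->'): ", string)
  parse_side <- function(side) {
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0)
      stop("malformed reaction (empty side): ", string)
    out <- character(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_.']*)$", tm))[[1]]
      if (length(m) != 3) stop("malformed species term '", tm, "' in: ", string)
      k <- if (nzchar(m[2])) as.integer(m[2]) else 1L
      out <- c(out, rep(m[3], k))
    }
    out
  }
  list(reactants = parse_side(sides[1]),
       products = parse_side(sides[2]),
       rate = rate)
}

#' @export
print.crn <- function(x, ...) {
  cat("Chemical reaction network:", length(x$species), "species,",
      nrow(x$reactant_mat), "reactions\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (i in seq_along(x$reaction_strings))
    cat(sprintf("  [%d] %s\n", i, x$reaction_strings[i]))
  cat("  absorbing A: all zero of {", paste(x$absorbing$A, collapse = ", "),
      "}; absorbing B: all zero of {", paste(x$absorbing$B, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Does every reaction conserve the total molecule count?
#' @param x a `crn`.
#' @return logical scalar.
#' @export
is_conservative <- function(x) {
  stopifnot(inherits(x, "crn"))
  all(rowSums(x$net_mat) == 0L)
}

# Coerce a user-supplied state (named or positional) to the CRN species order.
as_state <- function(x, state) {
  if (!is.null(names(state))) {
    bad <- setdiff(names(state), x$species)
    if (length(bad))
      stop("state names unknown species: ", paste(bad, collapse = ", "))
    full <- stats::setNames(integer(length(x$species)), x$species)
    full[names(state)] <- as.integer(state)
    state <- full
  } else {
    if (length(state) != length(x$species))
      stop("unnamed state must have one count per species")
    state <- stats::setNames(as.integer(state), x$species)
  }
  if (any(is.na(state)) || any(state < 0))
    stop("species counts must be non-negative integers")
  state
}

#' Mass-action propensities
#'
#' Computes the propensity of each reaction in the given state with the
#' reaction volume fixed at 1: `rate * n` for a unimolecular reaction,
#' `rate * n1 * n2` for a bimolecular reaction with distinct reactants, and
#' the `rate * n * (n - 1)` convention for two identical reactants (the
#' canonical switch library uses distinct reactants only).
#'
#' @param x a `crn`.
#' @param state named (or species-ordered) vector of non-negative counts.
#' @return numeric vector of propensities, one per reaction.
#' @export
propensities <- function(x, state) {
  stopifnot(inherits(x, "crn"))
  state <- as_state(x, state)
  n_rxn <- nrow(x$reactant_mat)
  a <- numeric(n_rxn)
  for (r in seq_len(n_rxn)) {
    val <- x$rates[r]
    for (s in seq_along(x$species)) {
      c_s <- x$reactant_mat[r, s]
      if (c_s > 0) {
        n <- state[s]
        # falling factorial n (n-1) ... (n-c+1)
        val <- val * prod(n - seq_len(c_s) + 1)
      }
    }
    a[r] <- max(val, 0)
  }
  a
}

outcome_levels <- c("A", "B", "deadlock", "censored")

#' Simulate a CRN to absorption (embedded jump chain)
#'
#' Runs the discrete-time jump chain of the Gillespie algorithm: at each step
#' the next reaction is sampled with probability proportional to its
#' mass-action propensity. Exponential waiting times are not generated, since
#' switching is taken to be instantaneous relative to the cell cycle; time is
#' measured in reaction counts. The run terminates when an absorbing predicate
#' holds, when total propensity is zero (a deadlock, reported rather than
#' raised), or after `max_events` reactions (censored).
#'
#' @param x a `crn`.
#' @param initial initial state (named vector of counts).
#' @param seed optional integer seed; identical seeds give identical
#'   trajectories.
#' @param max_events event cap (default `1e6`).
#' @param record if `TRUE` (default) record the full state sequence.
#' @return a `crn_trajectory`: list with `outcome` (factor: A, B, deadlock,
#'   censored), `n_events`, `final_state`, and when recorded `states` (matrix,
#'   one row per step starting at the initial state) and `reaction_indices`.
#' @examples
#' dc <- make_switch("DC", gmax = 60)
#' tr <- gillespie_run(dc$crn, c(x = 30, y = 30), seed = 1)
#' tr$outcome
#' @export
gillespie_run <- function(x, initial, seed = NULL, max_events = 1e6,
                          record = TRUE) {
  stopifnot(inherits(x, "crn"), max_events > 0)
  initial <- as_state(x, initial)
  if (!is.null(seed)) set.seed(seed)
  idx0 <- function(nm) match(nm, x$species) - 1L
  res <- .gillespie_core(x$reactant_mat, x$net_mat, x$rates,
                         unname(initial),
                         idx0(x$absorbing$A), idx0(x$absorbing$B),
                         as.integer(max_events), isTRUE(record))
  out <- list(
    outcome = factor(outcome_levels[res$outcome_code + 1L],
                     levels = outcome_levels),
    n_events = res$n_events,
    final_state = stats::setNames(res$final_state, x$species),
    species = x$species)
  if (isTRUE(record)) {
    colnames(res$states) <- x$species
    out$states <- res$states
    out$reaction_indices <- res$reaction_indices
  }
  class(out) <- "crn_trajectory"
  out
}

#' Replicated outcome-only CRN runs
#'
#' Runs `n` independent jump-chain simulations from a common initial state and
#' returns only the outcomes and event counts (much faster than recording full
#' trajectories when estimating switching frequencies).
#'
#' @inheritParams gillespie_run
#' @param n number of replicate runs.
#' @return data.frame with columns `outcome` (factor) and `n_events`.
#' @export
gillespie_outcomes <- function(x, initial, n, seed = NULL, max_events = 1e6) {
  stopifnot(inherits(x, "crn"), n >= 1)
  initial <- as_state(x, initial)
  if (!is.null(seed)) set.seed(seed)
  idx0 <- function(nm) match(nm, x$species) - 1L
  res <- .gillespie_outcomes_core(x$reactant_mat, x$net_mat, x$rates,
                                  unname(initial),
                                  idx0(x$absorbing$A), idx0(x$absorbing$B),
                                  as.integer(max_events), as.integer(n))
  data.frame(outcome = factor(outcome_levels[res$outcomes + 1L],
                              levels = outcome_levels),
             n_events = res$n_events)
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("CRN trajectory:", x$n_events, "reactions, outcome", as.character(x$outcome), "\n")
  cat("  final state:",
      paste(sprintf("%s=%d", names(x$final_state), x$final_state),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.crn_trajectory <- function(x, ...) {
  if (is.null(x$states))
    stop("trajectory was run with record = FALSE")
  df <- as.data.frame(x$states)
  df <- cbind(event = seq_len(nrow(df)) - 1L, df)
  df
}
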