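test_that("reaction strings parse to multisets and rates", {
  r <- parse_reaction("x + y -> x + x @ 1.5")
  expect_equal(sort(r$reactants), c("x", "y"))
  expect_equal(r$products, c("x", "x"))
  expect_equal(r$rate, 1.5)

  r2 <- parse_reaction("2x -> x + y")      # coefficient shorthand, default rate
  expect_equal(r2$reactants, c("x", "x"))
  expect_equal(r2$rate, 1)

  expect_error(parse_reaction("x + y -> @ 1"), "malformed")
  expect_error(parse_reaction("x y -> x + x"), "malformed")
  expect_error(parse_reaction("x -> x @ fast"), "malformed rate")
})

test_that("crn construction validates species and rates", {
  expect_error(crn("x + z -> x + x @ 1", absorbing = list(A = "y", B = "x"),
                   species = c("x", "y")),
               "not in the species list")
  expect_error(crn("x + y -> x + x @ -2", absorbing = list(A = "y", B = "x")),
               "positive")
  expect_error(crn("x + y -> x + x @ 1", absorbing = list(A = "q", B = "x")),
               "unknown species")
  net <- make_switch("DC")$crn
  expect_true(is_conservative(net))
})

test_that("mass-action propensities follow the count products", {
  dc <- make_switch("DC")
  expect_equal(propensities(dc$crn, c(x = 30, y = 30)), c(900, 900))
  expect_equal(propensities(dc$crn, c(x = 60, y = 0)), c(0, 0))

  k <- 1.7
  dcx <- make_switch("DCx", bias = k)
  expect_equal(propensities(dcx$crn, c(x = 1, y = 1)), c(k, 1))

  # identical-reactant convention: rate * n * (n - 1)
  dimer <- crn(c("x + x -> x + y @ 2"), absorbing = list(A = "y", B = "x"))
  expect_equal(propensities(dimer, c(x = 5, y = 0)), 2 * 5 * 4)
})

test_that("runs from an absorbed state terminate immediately", {
  dc <- make_switch("DC")
  tr <- gillespie_run(dc$crn, c(x = 60, y = 0), seed = 1)
  expect_equal(tr$n_events, 0)
  expect_equal(as.character(tr$outcome), "A")
  expect_equal(nrow(tr$states), 1)
})

test_that("molecule totals are conserved along every trajectory", {
  for (kind in c("DC", "AM", "DCdup")) {
    sw <- make_switch(kind, gmax = 30)
    tr <- gillespie_run(sw$crn, sw$embed(15), seed = 42)
    expect_true(all(rowSums(tr$states) == 30),
                label = paste(kind, "conservation"))
    expect_true(as.character(tr$outcome) %in% c("A", "B"))
    expect_equal(length(tr$reaction_indices), nrow(tr$states) - 1)
  }
})

test_that("identical seeds give identical trajectories", {
  am <- make_switch("AM")
  t1 <- gillespie_run(am$crn, am$embed(30), seed = 99)
  t2 <- gillespie_run(am$crn, am$embed(30), seed = 99)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$reaction_indices, t2$reaction_indices)
  t3 <- gillespie_run(am$crn, am$embed(30), seed = 100)
  expect_false(identical(t1$states, t3$states))
})

test_that("deadlocks are reported, not raised", {
  # the single reaction burns x and y; the resulting all-b state satisfies
  # neither predicate and has zero propensity
  toy <- crn("x + y -> b + b @ 1",
             absorbing = list(A = c("y", "b"), B = c("x", "b")))
  tr <- gillespie_run(toy, c(x = 1, y = 1, b = 0), seed = 1)
  expect_equal(as.character(tr$outcome), "deadlock")
  expect_equal(tr$n_events, 1)
})

test_that("event caps censor rather than absorb", {
  dc <- make_switch("DC")
  tr <- gillespie_run(dc$crn, c(x = 30, y = 30), seed = 5, max_events = 3)
  expect_equal(as.character(tr$outcome), "censored")
  expect_equal(tr$n_events, 3)
})

test_that("interior starts essentially always absorb within the default cap", {
  # almost-sure absorption: no deadlocks/censoring across the library
  for (kind in c("DC", "DCx", "DCy", "AM", "DCdup")) {
    sw <- make_switch(kind, gmax = 20)
    out <- gillespie_outcomes(sw$crn, sw$embed(10), n = 300, seed = 11)
    expect_true(all(out$outcome %in% c("A", "B")),
                label = paste(kind, "absorbs"))
  }
})

test_that("trajectories export as event-indexed data frames", {
  dc <- make_switch("DC")
  tr <- gillespie_run(dc$crn, c(x = 30, y = 30), seed = 1)
  df <- as.data.frame(tr)
  expect_equal(names(df), c("event", "x", "y"))
  expect_equal(df$event[1], 0)
  expect_equal(nrow(df), tr$n_events + 1)
})
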