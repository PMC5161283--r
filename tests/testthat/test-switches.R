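test_that("library switches have the canonical structure", {
  dc <- make_switch("DC")
  expect_equal(length(dc$crn$species), 2)
  expect_equal(length(dc$crn$rates), 2)
  expect_true(all(dc$crn$rates == 1))

  am <- make_switch("AM")
  expect_equal(length(am$crn$species), 3)
  expect_equal(length(am$crn$rates), 4)

  dup <- make_switch("DCdup")
  expect_equal(length(dup$crn$species), 4)
  expect_equal(length(dup$crn$rates), 8)
  expect_setequal(dup$crn$absorbing$A, c("y", "yp"))
  expect_setequal(dup$crn$absorbing$B, c("x", "xp"))

  expect_error(make_switch("XYZ"))
})

test_that("genotype embedding conserves the molecule total", {
  for (kind in c("DC", "DCx", "DCy", "AM", "DCdup")) {
    sw <- make_switch(kind)
    expect_equal(sum(sw$embed(17)), 60, label = kind)
  }
  g <- genotype(23)
  expect_equal(g$y0, 37)
  expect_error(genotype(61), "x0 must lie")
})

test_that("gambler's ruin matches brute-force enumeration", {
  # fair walk
  h_fair <- oracle_walk_absorption(12, p_up = 0.5)
  expect_equal(gamblers_ruin_probability(0:12, 12, r = 1), h_fair,
               tolerance = 1e-10)
  # biased walk: up-step probability k/(k+1) corresponds to r = 1/k
  k <- 1.3
  h_bias <- oracle_walk_absorption(12, p_up = k / (k + 1))
  expect_equal(gamblers_ruin_probability(0:12, 12, r = 1 / k), h_bias,
               tolerance = 1e-10)
  # boundaries
  expect_equal(gamblers_ruin_probability(0, 60, 0.7), 0)
  expect_equal(gamblers_ruin_probability(60, 60, 0.7), 1)
  expect_equal(gamblers_ruin_probability(30, 60, 1), 0.5)
})

test_that("Markov-chain absorption agrees with the closed forms", {
  dc <- make_switch("DC")
  for (x0 in c(5, 20, 33, 55)) {
    expect_equal(absorption_probability(dc, c(x = x0, y = 60 - x0)),
                 x0 / 60, tolerance = 1e-10)
  }
  dcx <- make_switch("DCx")
  expect_equal(absorption_probability(dcx, c(x = 7, y = 53)),
               hedge_probability(dcx, 7), tolerance = 1e-10)

  am <- make_switch("AM")
  expect_equal(absorption_probability(am, c(x = 30, y = 30, b = 0)), 0.5,
               tolerance = 1e-9)
  expect_equal(absorption_probability(am, c(x = 60, y = 0, b = 0)), 1)

  # non-conservative networks are rejected
  bad <- crn("x -> x + x @ 1", absorbing = list(A = "y", B = "x"),
             species = c("x", "y"))
  expect_error(absorption_probability(bad, c(x = 1, y = 1)), "conserve")
})

test_that("calibrated biased switches put the near-even hedge at 7 and 53", {
  dcx <- make_switch("DCx")
  dcy <- make_switch("DCy")
  expect_equal(round(hedge_probability(dcx, 7), 2), 0.49)
  expect_equal(round(hedge_probability(dcy, 53), 2), 0.51)
  expect_equal(closest_to_half(dcx), 7)
  expect_equal(closest_to_half(dcy), 53)
  expect_equal(closest_to_half(make_switch("DC")), 30)
})

test_that("hedge probabilities are symmetric and monotone", {
  x0 <- 0:60
  dc <- make_switch("DC")
  am <- make_switch("AM")
  p_dc <- hedge_probability(dc, x0)
  p_am <- hedge_probability(am, x0)
  expect_equal(p_dc, rev(1 - p_dc), tolerance = 1e-12)
  expect_equal(p_am, rev(1 - p_am), tolerance = 1e-8)
  for (kind in c("DC", "DCx", "DCy", "AM", "DCdup")) {
    p <- hedge_probability(make_switch(kind), x0)
    # strictly increasing wherever the increments are representable; the AM
    # tail saturates at 1 in double precision
    interior <- p < 1 - 1e-12
    expect_true(all(diff(p[interior]) > 0),
                label = paste(kind, "strictly increasing"))
    expect_true(all(diff(p) >= 0), label = paste(kind, "non-decreasing"))
    expect_equal(p[1], 0, tolerance = 1e-12)
    expect_equal(p[61], 1, tolerance = 1e-12)
  }
})

test_that("AM switching probability is reflection-symmetric in x and y", {
  am <- make_switch("AM", gmax = 20)
  p1 <- absorption_probability(am, c(x = 6, y = 10, b = 4))
  p2 <- absorption_probability(am, c(x = 10, y = 6, b = 4))
  expect_equal(p1, 1 - p2, tolerance = 1e-9)
})

test_that("DCdup switching equals DC on the summed counts", {
  dup <- make_switch("DCdup")
  # non-circular route: full Markov solve on the four-species network
  grid <- expand.grid(x = 0:3, xp = 0:3, y = 0:3, yp = 0:3)
  grid <- grid[rowSums(grid) > 0 & grid$x + grid$xp > 0 &
                 grid$y + grid$yp > 0, ]
  grid <- grid[seq(1, nrow(grid), by = 7), ]       # thin the grid
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ])
    expect_equal(
      absorption_probability(dup$crn, s),
      (s[["x"]] + s[["xp"]]) / sum(s),
      tolerance = 1e-10,
      label = paste(s, collapse = ","))
  }
  # the closed-form route agrees, and matches the flagship example
  expect_equal(switch_probability(dup, c(x = 20, xp = 30, y = 30, yp = 20)),
               0.5)
})

test_that("species deletion shifts but does not destroy the hedge", {
  dup <- make_switch("DCdup")
  red1 <- delete_species(dup, "x")
  expect_equal(length(red1$crn$species), 3)
  expect_equal(switch_probability(red1, c(xp = 30, y = 30, yp = 20)), 0.375)

  red2 <- delete_species(dup, c("x", "y"))
  expect_equal(switch_probability(red2, c(xp = 30, yp = 20)), 0.6)

  # mixed initial conditions stay strictly hedged after deletion
  for (del in list("x", "xp", c("x", "y"), c("xp", "yp"))) {
    red <- delete_species(dup, del)
    keep <- red$crn$species
    counts <- stats::setNames(rep(10, length(keep)), keep)
    p <- switch_probability(red, counts)
    expect_gt(p, 0); expect_lt(p, 1)
  }

  expect_error(delete_species(dup, c("x", "xp")), "degenerate")
  expect_error(delete_species(dup, "nope"), "unknown species")
})

test_that("simulated outcome frequencies match analytic probabilities", {
  n <- 3000
  for (kind in c("DC", "DCx", "AM")) {
    sw <- make_switch(kind)
    for (x0 in c(10, 30, 50)) {
      p <- hedge_probability(sw, x0)
      out <- gillespie_outcomes(sw$crn, sw$embed(x0), n = n,
                                seed = 1000 + x0)
      freq <- mean(out$outcome == "A")
      se <- sqrt(p * (1 - p) / n)
      # 3.5 SE: family-wise allowance over the 9 (switch, genotype) cells
      expect_lt(abs(freq - p), 3.5 * se + 1e-12,
                label = sprintf("%s x0=%d", kind, x0))
    }
  }
})

test_that("probability tables and grids cover genotype space", {
  tab <- switch_prob_table(make_switch("DC"))
  expect_equal(nrow(tab), 61)
  expect_equal(tab$x0 + tab$y0, rep(60, 61))
  expect_equal(tab$p, tab$x0 / 60)

  grid <- switch_prob_grid(make_switch("DCy"), n = 8)
  expect_equal(nrow(grid), 64)
  r <- make_switch("DCy")$bias
  expect_equal(grid$p[grid$x0 == 3 & grid$y0 == 5],
               gamblers_ruin_probability(3, 8, r))
})
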