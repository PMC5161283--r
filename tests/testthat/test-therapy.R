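test_that("drug regimes carry the preset parameters", {
  cs <- drug_regime("cytostatic")
  expect_equal(c(cs$dA, cs$fA), c(0.005, 0))
  ct <- drug_regime("cytotoxic")
  expect_equal(c(ct$dA, ct$fA), c(0.8, 1.0))
  mx <- drug_regime("mixed")
  expect_equal(c(mx$dA, mx$fA), c(0.4, 0.5))
  # phenotype B is drug-impervious in every preset
  for (r in list(cs, ct, mx))
    expect_equal(c(r$dB, r$fB), c(0.005, 0.015))
  expect_error(drug_regime("custom", dA = 1.3, fA = 0.1), "lie in")
  expect_error(drug_regime("custom"), "requires")
})

test_that("cytostatic extinction threshold is ~0.005 at background death", {
  expect_equal(cytostatic_threshold(0.005), 1 / 0.995 - 1)
  expect_equal(cytostatic_threshold(0.005), 0.005, tolerance = 1e-2)
  # below threshold the treated A-compartment declines, above it grows
  expect_lt(offspring_number(0.005, cytostatic_threshold(0.005) * 0.9), 1)
  expect_gt(offspring_number(0.005, cytostatic_threshold(0.005) * 1.1), 1)
})

test_that("post-holiday genotype accumulates expected fixation waits", {
  dcy <- make_switch("DCy")
  expect_equal(post_holiday_genotype(dcy, 53, 0)$x0, 53)
  ph <- post_holiday_genotype(dcy, 53, 3000)
  expect_equal(ph$x0, 60)
  expect_equal(ph$p, 1)
  expect_lt(ph$events_used, 3000)
  # non-decreasing in T
  Ts <- c(0, 50, 200, 1000, 3000)
  gs <- vapply(Ts, function(T) post_holiday_genotype(dcy, 53, T)$x0,
               numeric(1))
  expect_true(all(diff(gs) >= 0))
  # AM freezes where steps become effectively neutral
  am <- make_switch("AM")
  frozen <- post_holiday_genotype(am, 30, 1e12)$x0
  expect_lt(frozen, 60)
  expect_equal(post_holiday_genotype(am, 30, 1e15)$x0, frozen)
})

test_that("certain death empties every replicate in one hour", {
  reg <- drug_regime("custom", dA = 1, fA = 0, dB = 1, fB = 0)
  out <- treatment_simulation(0.5, reg, N0 = 1e4, horizon = 240,
                              replicates = 10, seed = 1)
  expect_true(all(out$extinct))
  expect_true(all(out$t_ext == 1))
  expect_true(all(out$successful))
})

test_that("pure-A cytotoxic decline matches the deterministic rate", {
  # mean log-decline per hour is log((1-0.8)(1+1)) = log 0.4
  out <- treatment_simulation(1, drug_regime("cytotoxic"), N0 = 1e6,
                              horizon = 240, replicates = 40, seed = 7)
  expect_true(all(out$extinct))
  predicted <- log(1e6) / log(2.5)
  expect_lt(abs(mean(out$t_ext) - predicted), 3)
})

test_that("compartment updates match an individual-based simulation", {
  # declining regime so extinction times are informative
  reg <- drug_regime("custom", dA = 0.6, fA = 0.2, dB = 0.3, fB = 0.1)
  p <- 0.5; N0 <- 300; n <- 120
  comp <- treatment_simulation(p, reg, N0 = N0, horizon = 500,
                               replicates = n, seed = 21,
                               success_threshold = 240)
  set.seed(22)
  indiv <- vapply(seq_len(n), function(i)
    oracle_individual_treatment(p, reg, N0, horizon = 500), numeric(1))
  expect_true(all(comp$extinct))
  expect_true(all(!is.na(indiv)))
  ks <- suppressWarnings(stats::ks.test(comp$t_ext, indiv))
  expect_gt(ks$p.value, 0.01)
})

test_that("supercritical treated populations are flagged and persist", {
  reg <- drug_regime("cytostatic")
  out <- treatment_simulation(0.5, reg, N0 = 1e6, horizon = 300,
                              replicates = 10, seed = 4)
  expect_gt(attr(out, "drug_mean_fitness"), 1)
  expect_true(all(!out$extinct))
  expect_true(all(out$t_ext == 300))
})

test_that("holiday sweeps classify conditions monotonically for DC", {
  sw <- make_switch("DC")
  res <- holiday_sweep(sw, 30, T_list = c(0, 5000),
                       regime = drug_regime("cytotoxic"),
                       N0 = 1e8, horizon = 2000, replicates = 30, seed = 9)
  expect_equal(res$classification, c("no_extinction", "successful"))
  expect_true(all(diff(res$p) >= 0))
  # success is monotone in T here
  expect_true(all(diff(res$success_fraction) >= 0))
})
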