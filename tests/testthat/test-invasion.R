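test_that("neutral and deleterious mutants never fix", {
  env <- env_spec()
  expect_equal(fixation_probability(0.5, 0.5, env)$pi, 0)
  expect_equal(fixation_probability(0.5, 0.4, env)$pi, 0)
  expect_equal(fixation_probability(0.9, 0.1, env)$pi, 0)
  # zero iff subcritical, over a grid
  for (p1 in c(0.1, 0.5, 0.9)) {
    for (p2 in c(0.05, 0.5, 0.95)) {
      res <- fixation_probability(p1, p2, env)
      if (p2 <= p1) {
        expect_equal(res$pi, 0)
        expect_false(res$supercritical)
      } else {
        expect_gt(res$pi, 0)
        expect_true(res$supercritical)
      }
    }
  }
})

test_that("fixation probability is increasing in the invader hedge", {
  env <- env_spec()
  p2 <- seq(0.51, 1, by = 0.07)
  pi <- vapply(p2, function(q) fixation_probability(0.5, q, env)$pi,
               numeric(1))
  expect_true(all(diff(pi) > 0))
})

test_that("the proliferative founder phenotype fixes more often", {
  env <- env_spec()
  res <- fixation_probability(0.5, 0.7, env)
  expect_gte(res$pi_A, res$pi_B)
  expect_equal(res$pi, 0.7 * res$pi_A + 0.3 * res$pi_B, tolerance = 1e-12)
})

test_that("the solved root satisfies the defining fixed-point identity", {
  env <- env_spec()
  for (p2 in c(0.52, 0.7, 0.99)) {
    res <- fixation_probability(0.5, p2, env)
    wbar <- mean_fitness(0.5, env)
    # 1 - pi_j = exp(-(w_j/<w>) * (p2 pi_A + (1-p2) pi_B))
    S <- p2 * res$pi_A + (1 - p2) * res$pi_B
    expect_equal(1 - res$pi_A, exp(-env$wA / wbar * S), tolerance = 1e-9)
    expect_equal(1 - res$pi_B, exp(-env$wB / wbar * S), tolerance = 1e-9)
  }
})

test_that("equal offspring numbers reduce to single-type Poisson survival", {
  # when wB -> wA, pi depends only on lambda' and solves 1 - s = exp(-l s)
  env <- env_spec(wA = 1.8, wB = 1.8)
  p1 <- 0.3; p2 <- 0.8
  lambda <- mean_fitness(p2, env) / mean_fitness(p1, env)  # = 1 here
  expect_equal(fixation_probability(p1, p2, env)$pi, 0)    # neutral limit

  # give the invader an edge via a resident normalisation < 1
  env2 <- env_spec(wA = 1.3, wB = 1.3 - 1e-9)
  res <- fixation_probability(0.2, 0.9, env2)
  l <- res$growth_factor
  s_oracle <- uniroot(function(s) 1 - s - exp(-l * s), c(1e-12, 1),
                      tol = 1e-14)$root
  expect_equal(res$pi, s_oracle, tolerance = 1e-7)
  expect_equal(res$pi_A, res$pi_B, tolerance = 1e-6)
})

test_that("fixation probability matches direct branching simulation", {
  env <- env_spec()
  p1 <- 0.5; p2 <- 31 / 60
  analytic <- fixation_probability(p1, p2, env)$pi
  set.seed(2024)
  n <- 1e5
  mc <- oracle_branching_mc(p1, p2, env, n_lineages = n)
  se <- sqrt(analytic * (1 - analytic) / n)
  expect_lt(abs(mc - analytic), 3 * se)
})

test_that("invasion grids are zero on and above the antidiagonal", {
  grid <- invasion_grid(p1 = seq(0.1, 0.9, by = 0.2),
                        p2 = seq(0.1, 0.9, by = 0.2))
  expect_true(all(grid$pi[grid$p2 <= grid$p1] == 0))
  expect_true(all(grid$pi[grid$p2 > grid$p1] > 0))
  # increasing toward the p2 = 1, p1 = 0 corner
  corner <- fixation_probability(0.1, 0.9)$pi
  mid <- fixation_probability(0.4, 0.6)$pi
  expect_gt(corner, mid)
})
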