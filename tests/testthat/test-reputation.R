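test_that("payoffs follow the benefit-minus-cost definition exactly", {
  # two players: 1 helps 2 always, 2 never helps back
  x <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(payoffs_from_coop(x, b = 5, c = 1), c(-1, 5))
  # full cooperation gives everyone b - c
  expect_equal(payoffs_from_coop(matrix(1, 5, 5), b = 5, c = 1), rep(4, 5))
  # random matrix against an independently coded double loop
  set.seed(1)
  x <- matrix(runif(16), 4, 4)
  expect_equal(payoffs_from_coop(x, b = 3.7, c = 1.2),
               payoffs_brute_force(x, 3.7, 1.2))
  expect_error(payoffs_from_coop(matrix(0, 2, 3), 5, 1), "square")
})

test_that("a single round behaves deterministically in the forced cases", {
  # homogeneous deterministic leading-eight population, all-good matrix,
  # no noise: the donor cooperates and nothing changes
  for (idx in 1:8) {
    cfg <- sim_config(rep(list(leading_eight(idx)), 5), q = 1, epsilon = 0,
                      T = 10, seed = 1)
    M <- matrix(1L, 5, 5)
    set.seed(idx)
    out <- reputation_step(M, cfg)
    expect_identical(out$record$action, "C")
    expect_equal(out$M, M)
  }

  # an ALLD donor always defects
  cfg <- sim_config(rep(list(alld()), 4), q = 1, epsilon = 0, T = 10, seed = 1)
  set.seed(3)
  out <- reputation_step(matrix(1L, 4, 4), cfg)
  expect_identical(out$record$action, "D")

  # epsilon = 1, q = 1: every observer perceives the flipped action; with an
  # all-good matrix the (actual C, perceived D, good recipient) context makes
  # every leading-eight observer assign a bad reputation to the donor
  cfg <- sim_config(rep(list(leading_eight(1)), 4), q = 1, epsilon = 1,
                    T = 10, seed = 1)
  set.seed(5)
  out <- reputation_step(matrix(1L, 4, 4), cfg)
  d <- out$record$donor
  expect_identical(out$record$action, "C")
  expect_equal(unname(out$M[-d, d]), rep(0L, 3))
  expect_equal(out$M[d, d], 1L)  # self-update uses the true action
})

test_that("simulated populations satisfy the conservation and fixed-point
           invariants", {
  # homogeneous ALLC: full cooperation, payoffs b - c
  cfg <- sim_config(rep(list(allc()), 6), b = 5, c = 1, q = 0.5,
                    epsilon = 0.3, T = 5e3, seed = 2)
  s <- simulate_reputation(cfg)
  expect_equal(s$coop_rate, 1)
  expect_equal(s$payoffs, rep(4, 6))

  # deterministic leading-eight fixed point: all-good stays all-good
  for (idx in 1:8) {
    cfg <- sim_config(rep(list(leading_eight(idx)), 6), q = 1, epsilon = 0,
                      T = 2e3, seed = idx)
    s <- simulate_reputation(cfg)
    expect_equal(s$coop_rate, 1)
    expect_equal(s$avg_image, matrix(1, 6, 6))
    expect_equal(s$final_image, matrix(1L, 6, 6))
  }

  # mixed noisy population: matrices stay within bounds, ALLD rows of the
  # cooperation matrix are exactly zero, ALLC rows exactly one where realized
  pop <- c(rep(list(leading_eight(1)), 3), rep(list(allc()), 3),
           rep(list(alld()), 3))
  cfg <- sim_config(pop, q = 0.9, epsilon = 0.05, T = 2e4, seed = 4)
  s <- simulate_reputation(cfg)
  expect_true(all(s$avg_image >= 0 & s$avg_image <= 1))
  expect_true(all(s$coop_matrix >= 0 & s$coop_matrix <= 1))
  expect_true(all(s$final_image %in% c(0L, 1L)))
  alld_rows <- 7:9
  allc_rows <- 4:6
  expect_true(all(s$coop_matrix[alld_rows, ] == 0))
  realized <- s$interaction_count[allc_rows, -allc_rows] > 0
  expect_true(all((s$coop_matrix[allc_rows, -allc_rows] == 1)[realized]))
})

test_that("runs are reproducible from the seed", {
  pop <- thirds_population(leading_eight(2), N = 9)
  cfg <- sim_config(pop, q = 0.9, epsilon = 0.05, T = 1e4, seed = 77)
  s1 <- simulate_reputation(cfg)
  s2 <- simulate_reputation(cfg)
  expect_identical(s1$avg_image, s2$avg_image)
  expect_identical(s1$payoffs, s2$payoffs)
  cfg$seed <- 78
  s3 <- simulate_reputation(cfg)
  expect_false(identical(s1$avg_image, s3$avg_image))
})

test_that("the exact image-matrix chain matches its closed forms", {
  # homogeneous deterministic L1 without noise: the all-good state absorbs
  cfg <- sim_config(rep(list(leading_eight(1)), 2), q = 1, epsilon = 0,
                    T = 10, seed = 1)
  ex <- exact_stationary_small(cfg)
  expect_equal(ex$distribution[length(ex$distribution)], 1)
  expect_equal(ex$image_expectation, matrix(1, 2, 2))
  expect_equal(rowSums(ex$W), rep(1, 16))

  # with assessment generosity the long-run good image held of an ALLD
  # co-player is strictly positive
  cfg_g <- sim_config(list(make_generous(leading_eight(1), 0.1, 0), alld()),
                      q = 0.9, epsilon = 0, T = 10, seed = 1)
  ex_g <- exact_stationary_small(cfg_g)
  expect_gt(ex_g$image_expectation[1, 2], 0)

  expect_error(
    exact_stationary_small(sim_config(rep(list(allc()), 4), T = 10)),
    "N <= 3")
})

test_that("simulated long-run image frequencies agree with exact enumeration
           for tiny populations", {
  configs <- list(
    sim_config(list(leading_eight(1), alld()), q = 0.9, epsilon = 0.05,
               T = 2e4, seed = 1),
    sim_config(list(leading_eight(1), leading_eight(1), alld()), q = 0.9,
               epsilon = 0.05, T = 2e4, seed = 1),
    sim_config(list(make_generous(leading_eight(6), 0.05, 0.05), allc(),
                    alld()), q = 0.8, epsilon = 0.1, T = 2e4, seed = 1)
  )
  for (cfg in configs) {
    ex <- exact_stationary_small(cfg)
    reps <- 16
    sims <- lapply(seq_len(reps), function(r) {
      cfg$seed <- 1000 + r
      simulate_reputation(cfg)$avg_image
    })
    mean_img <- Reduce(`+`, sims) / reps
    se_img <- sqrt(Reduce(`+`, lapply(sims, function(s)
      (s - mean_img)^2)) / (reps * (reps - 1)))
    dev <- abs(mean_img - ex$image_expectation)
    expect_true(all(dev <= 3 * se_img + 1e-9))
  }
})
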