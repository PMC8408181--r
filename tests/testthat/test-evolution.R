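test_that("the fixation probability matches its closed forms", {
  # neutral mutant and vanishing selection both give 1/N
  expect_equal(fixation_probability(rep(1, 9), rep(1, 9), beta = 1), 0.1)
  set.seed(1)
  piM <- runif(9); piR <- runif(9)
  expect_equal(fixation_probability(piM, piR, beta = 0), 0.1)
  # N = 3 with constant advantage delta: 1/(1 + e^-bd + e^-2bd)
  expect_equal(fixation_probability(c(2, 2), c(1, 1), beta = 1),
               1 / (1 + exp(-1) + exp(-2)))
  # random profiles against direct summation
  for (r in 1:5) {
    piM <- rnorm(7, sd = 2); piR <- rnorm(7, sd = 2)
    expect_equal(fixation_probability(piM, piR, beta = 0.7),
                 fixation_direct(piM, piR, 0.7))
  }
  expect_error(fixation_probability(1:3, 1:4, 1), "equal length")
})

test_that("fixation is monotone in payoff advantage and stable under strong
           selection", {
  set.seed(2)
  piR <- rnorm(9)
  shifts <- seq(-2, 2, by = 0.5)
  rho <- vapply(shifts, function(d)
    fixation_probability(piR + d, piR, beta = 1), 1)
  expect_true(all(diff(rho) > 0))
  # large |beta * delta| must not overflow or underflow to NaN
  lo <- fixation_probability(rep(0, 49), rep(50, 49), beta = 20)
  hi <- fixation_probability(rep(50, 49), rep(0, 49), beta = 20)
  expect_true(is.finite(lo) && lo >= 0 && lo < 1e-100)
  expect_true(hi <= 1 && hi > 1 - 1e-12)
})

test_that("the rare-mutation transition matrix is the half-fixation embedding",
{
  rho <- matrix(0, 3, 3,
                dimnames = list(mutant = c("L", "ALLC", "ALLD"),
                                resident = c("L", "ALLC", "ALLD")))
  rho[1, 2] <- 0.1; rho[1, 3] <- 0.2   # L invades ALLC / ALLD
  rho[2, 1] <- 0.3; rho[2, 3] <- 0.4
  rho[3, 1] <- 0.5; rho[3, 2] <- 0.6
  W <- transition_matrix(rho)
  expect_equal(rowSums(W), stats::setNames(rep(1, 3), rownames(W)))
  # leaving state L toward ALLC happens via an ALLC mutant fixing in L
  expect_equal(W["L", "ALLC"], rho["ALLC", "L"] / 2)
  expect_equal(W["ALLD", "L"], rho["L", "ALLD"] / 2)

  # all fixation probabilities at the neutral value: doubly stochastic,
  # uniform stationary distribution
  rho_n <- matrix(1 / 50, 3, 3)
  W_n <- transition_matrix(rho_n)
  expect_equal(colSums(W_n), rep(1, 3))
  expect_equal(unname(stationary_distribution(W_n)), rep(1 / 3, 3))

  bad <- rho; bad[1, 2] <- 1.4
  expect_error(transition_matrix(bad), "\\[0, 1\\]")
})

test_that("the stationary distribution solves pi W = pi", {
  # two-state chain with one transition twice as likely as the reverse
  W2 <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE)
  expect_equal(unname(stationary_distribution(W2)), c(2, 1) / 3)
  # random stochastic matrices against a power-iteration oracle
  set.seed(3)
  for (r in 1:5) {
    W <- matrix(rexp(9), 3, 3)
    W <- W / rowSums(W)
    p <- stationary_distribution(W)
    expect_lt(max(abs(as.numeric(p %*% W) - p)), 1e-12)
    expect_equal(unname(p), stationary_power_iteration(W), tolerance = 1e-9)
  }
  expect_error(stationary_distribution(matrix(c(1, 1, 0, 1), 2, 2)),
               "row-stochastic")
})

test_that("the stationary distribution is equivariant under relabeling of the
           three norms", {
  set.seed(4)
  W <- matrix(rexp(9), 3, 3); W <- W / rowSums(W)
  p <- unname(stationary_distribution(W))
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    Wp <- W[perm, perm]
    expect_equal(unname(stationary_distribution(Wp)), p[perm],
                 tolerance = 1e-12)
  }
})

test_that("equilibrium cooperation is the abundance-weighted average", {
  expect_equal(equilibrium_cooperation(c(0, 0, 1), c(0.9, 1, 0)), 0)
  expect_equal(equilibrium_cooperation(c(0, 1, 0), c(0.9, 1, 0)), 1)
  expect_equal(equilibrium_cooperation(c(0.5, 0.5, 0), c(0.9, 1, 0)), 0.95)
  expect_error(equilibrium_cooperation(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("pairwise payoffs of defectors against cooperators follow the
           closed form", {
  N <- 6
  cfg <- evo_config(list(leading_eight(1), allc(), alld()), N = N, b = 5,
                    c = 1, q = 0.9, epsilon = 0.05, rep_T = 5e4,
                    replicates = 1, seed = 9)
  prof <- pairwise_payoffs(alld(), allc(), cfg)
  # with every ordered pair realized, ALLC donors cooperate always and ALLD
  # donors never, so payoffs are exact rational numbers
  expect_equal(prof$pi_A, 5 * (N - seq_len(N - 1)) / (N - 1))
  expect_equal(prof$pi_B, (5 * (N - seq_len(N - 1) - 1) - (N - 1)) / (N - 1))
  expect_true(all(prof$pi_A > prof$pi_B))
  expect_error(pairwise_payoffs(allc(), allc(), cfg), "distinct")
})

test_that("identical competitors are neutral: fixation equals 1/N", {
  N <- 6
  allc2 <- allc(); allc2$name <- "ALLC2"
  cfg <- evo_config(list(leading_eight(1), allc(), alld()), N = N, b = 5,
                    c = 1, q = 0.9, epsilon = 0.05, rep_T = 2e4,
                    replicates = 1, seed = 10)
  prof <- pairwise_payoffs(allc(), allc2, cfg)
  expect_equal(prof$pi_A, prof$pi_B)
  expect_equal(fixation_probability(prof$pi_A, prof$pi_B, beta = 1), 1 / N)
})

test_that("with zero selection strength the equilibrium is uniform", {
  cfg <- evo_config(list(leading_eight(1), allc(), alld()), N = 8, s = 0,
                    b = 5, c = 1, q = 0.9, epsilon = 0.05, rep_T = 2e3,
                    replicates = 1, seed = 11)
  ev <- run_evolution(cfg)
  expect_equal(unname(ev$stationary), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(ev$rho[row(ev$rho) != col(ev$rho)]), rep(1 / 8, 6))
  expect_equal(ev$homogeneous_coop_rates[["ALLC"]], 1)
  expect_equal(ev$homogeneous_coop_rates[["ALLD"]], 0)
})

test_that("payoff profiles are cached and reused", {
  cache <- file.path(tempdir(), "le-cache-test")
  on.exit(unlink(cache, recursive = TRUE), add = TRUE)
  cfg <- evo_config(list(leading_eight(1), allc(), alld()), N = 4, b = 5,
                    c = 1, q = 0.9, epsilon = 0.05, rep_T = 2e3,
                    replicates = 1, seed = 12, cache_dir = cache)
  p1 <- pairwise_payoffs(allc(), alld(), cfg)
  files <- list.files(cache)
  expect_length(files, 1)
  p2 <- pairwise_payoffs(allc(), alld(), cfg)
  expect_equal(p1, p2)
  expect_length(list.files(cache), 1)
})
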