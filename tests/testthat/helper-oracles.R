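# Independent oracles and small fixture builders used across the test files.

# brute-force double-loop evaluation of the payoff definition
payoffs_brute_force <- function(coop_matrix, b, c) {
  n <- nrow(coop_matrix)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      s <- s + b * coop_matrix[j, i] - c * coop_matrix[i, j]
    }
    out[i] <- s / (n - 1)
  }
  out
}

# stationary distribution by long power iteration, independent of the
# linear-solve route used by the package
stationary_power_iteration <- function(W, iters = 200000) {
  v <- rep(1 / nrow(W), nrow(W))
  for (i in seq_len(iters)) {
    v_new <- as.numeric(v %*% W)
    if (max(abs(v_new - v)) < 1e-15) return(v_new)
    v <- v_new
  }
  v
}

# direct summation of the fixation formula, no log-space tricks
fixation_direct <- function(pi_M, pi_R, beta) {
  n <- length(pi_M) + 1
  total <- 1
  for (i in seq_len(n - 1)) {
    prod_i <- 1
    for (k in seq_len(i)) prod_i <- prod_i * exp(-beta * (pi_M[k] - pi_R[k]))
    total <- total + prod_i
  }
  1 / total
}

# population of one third each: the given norm, ALLC and ALLD
thirds_population <- function(norm, N = 90) {
  stopifnot(N %% 3 == 0)
  c(rep(list(norm), N / 3), rep(list(allc()), N / 3), rep(list(alld()), N / 3))
}

# block means of the average image for the mixed population, as percentages
mixed_image_stats <- function(norm, epsilon, q, T, seed, N = 90) {
  cfg <- sim_config(thirds_population(norm, N), b = 5, c = 1, q = q,
                    epsilon = epsilon, T = T, seed = seed)
  sim <- simulate_reputation(cfg)
  blocks <- block_average(sim$avg_image, sim$norm_names)
  list(within_bad = 100 * (1 - blocks[1, 1]),
       within_good = 100 * blocks[1, 1],
       to_alld_good = 100 * blocks[1, 3],
       sim = sim)
}
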