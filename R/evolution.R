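# Evolutionary dynamics in the rare-mutation limit: pairwise fixation
# probabilities from simulated mixed populations, the three-state Markov
# chain over homogeneous populations, and its stationary distribution.

#' Configuration of an evolutionary competition
#'
#' Describes the rare-mutation competition between three social norms: a
#' (possibly generous) leading-eight norm, unconditional cooperation and
#' unconditional defection.  Norms spread by a pairwise-comparison (Fermi)
#' imitation process with selection strength \code{s}; in the rare-mutation
#' limit the population is homogeneous almost always, and the dynamics
#' reduces to a three-state Markov chain whose transitions are fixation
#' probabilities of single mutants.
#'
#' @param norm_set list of exactly three \code{social_norm}s with distinct
#'   names, in the state order used throughout (leading-eight norm, ALLC,
#'   ALLD).
#' @param N population size of the evolving population.
#' @param s selection strength (\eqn{\beta} of the fixation formula).
#' @param b,c,q,epsilon donation-game parameters, as in [sim_config()].
#' @param rep_T rounds per reputation simulation used to estimate payoffs.
#' @param replicates independent reputation runs averaged per population
#'   composition.
#' @param seed master seed; every composition derives its own child seed.
#' @param cache_dir optional directory in which pairwise payoff profiles are
#'   cached as CSV, keyed by norms, parameters and seed.
#' @return An \code{evo_config} object.
#' @export
evo_config <- function(norm_set, N = 50, s = 1, b = 5, c = 1, q = 0.9,
                       epsilon = 0.05, rep_T = 1e6, replicates = 1,
                       seed = 1, cache_dir = NULL) {
  if (!is.list(norm_set) || length(norm_set) != 3 ||
      !all(vapply(norm_set, inherits, TRUE, "social_norm")))
    stop("norm_set must be a list of three social_norm objects", call. = FALSE)
  nms <- vapply(norm_set, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("norm names must be distinct", call. = FALSE)
  if (s < 0) stop("selection strength must be non-negative", call. = FALSE)
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  structure(list(norm_set = norm_set, norm_names = nms, N = N, s = s,
                 b = b, c = c, q = q, epsilon = epsilon,
                 rep_T = as.numeric(rep_T), replicates = replicates,
                 seed = as.numeric(seed), cache_dir = cache_dir),
            class = "evo_config")
}

# deterministic 31-bit child seed from a master seed and integer indices
.child_seed <- function(master, ...) {
  h <- master %% 2147483647
  for (x in c(...)) h <- (h * 69069 + x + 1) %% 2147483647
  h + 1
}

#' Payoffs along a mutant-resident mixture
#'
#' For every composition with \code{k} players of \code{normA} and
#' \code{N - k} players of \code{normB}, \code{k = 1, ..., N - 1}, simulates
#' the reputation dynamics and records the mean payoff of each group.  These
#' profiles feed the fixation-probability formula; in the rare-mutation limit
#' only two-norm mixtures ever occur, so the three unordered pairs of the
#' norm set suffice and each sweep serves both invasion directions.
#'
#' @param normA,normB two distinct \code{social_norm}s.
#' @param config an [evo_config()].
#' @return A data frame with columns \code{k}, \code{pi_A} (mean payoff of
#'   the \code{k} \code{normA} players) and \code{pi_B}.
#' @export
pairwise_payoffs <- function(normA, normB, config) {
  stopifnot(inherits(config, "evo_config"))
  if (identical(normA$name, normB$name))
    stop("norms must be distinct", call. = FALSE)
  cache_file <- NULL
  if (!is.null(config$cache_dir)) {
    key <- paste(normA$name, normB$name,
                 paste(signif(c(normA$assessment, normA$action,
                                normB$assessment, normB$action), 10),
                       collapse = "_"),
                 config$N, config$b, config$c, config$q, config$epsilon,
                 config$rep_T, config$replicates, config$seed, sep = "|")
    cache_file <- file.path(config$cache_dir,
                            paste0("payoffs_", .hash_key(key), ".csv"))
    if (file.exists(cache_file))
      return(utils::read.csv(cache_file))
  }
  N <- config$N
  pi_A <- pi_B <- numeric(N - 1)
  for (k in seq_len(N - 1)) {
    pa <- pb <- 0
    for (r in seq_len(config$replicates)) {
      seed_kr <- .child_seed(config$seed, match(normA$name, config$norm_names),
                             match(normB$name, config$norm_names), k, r)
      cfg <- sim_config(c(rep(list(normA), k), rep(list(normB), N - k)),
                        b = config$b, c = config$c, q = config$q,
                        epsilon = config$epsilon, T = config$rep_T,
                        seed = seed_kr)
      sim <- simulate_reputation(cfg)
      pa <- pa + mean(sim$payoffs[seq_len(k)])
      pb <- pb + mean(sim$payoffs[(k + 1):N])
    }
    pi_A[k] <- pa / config$replicates
    pi_B[k] <- pb / config$replicates
  }
  out <- data.frame(k = seq_len(N - 1), pi_A = pi_A, pi_B = pi_B)
  if (!is.null(cache_file)) {
    dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, cache_file, row.names = FALSE)
  }
  out
}

# short stable hash for cache file names (31-bit multiplicative hash)
.hash_key <- function(key) {
  h <- 17
  for (b in utf8ToInt(key)) h <- (bitwXor(h, b) * 69069 + 1) %% 2147483648
  sprintf("%08x", h)
}

#' Fixation probability of a mutant norm
#'
#' Evaluates
#' \deqn{\rho_{MR} = \left(1 + \sum_{i=1}^{N-1} \prod_{k=1}^{i}
#'   e^{-\beta(\pi_M(k) - \pi_R(k))}\right)^{-1}}
#' for a single mutant with payoff profile \eqn{\pi_M(k)} invading residents
#' with profile \eqn{\pi_R(k)}, where \eqn{k} counts mutants.  The products
#' are accumulated as cumulative sums in log space, so the result is stable
#' for large \eqn{|\beta \Delta\pi|}.  With \code{beta = 0} or identical
#' profiles the neutral value \eqn{1/N} is recovered.
#'
#' @param pi_M,pi_R numeric vectors of length \code{N - 1}: mean payoffs of
#'   mutants and residents when \code{k = 1, ..., N - 1} mutants are present.
#' @param beta selection strength (non-negative).
#' @return The fixation probability.
#' @examples
#' fixation_probability(rep(1, 9), rep(1, 9), beta = 1)  # neutral: 1/10
#' @export
fixation_probability <- function(pi_M, pi_R, beta) {
  if (length(pi_M) != length(pi_R))
    stop("payoff profiles must have equal length", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  logterms <- cumsum(-beta * (pi_M - pi_R))  # log of the partial products
  m <- max(0, logterms)
  # rho = exp(-m) / (exp(-m) + sum exp(logterms - m))
  exp(-m) / (exp(-m) + sum(exp(logterms - m)))
}

#' Rare-mutation transition matrix over three homogeneous populations
#'
#' Builds the row-stochastic matrix of the embedded Markov chain whose
#' states are the three homogeneous populations, in the order (L, ALLC,
#' ALLD).  A mutant of either other norm appears with probability 1/2, so
#' the off-diagonal entry from resident \code{r} to norm \code{m} is half
#' the fixation probability of an \code{m}-mutant in an \code{r}-resident
#' population; diagonals complete the rows to one.
#'
#' @param rho a 3 x 3 matrix with \code{rho[m, r]} the fixation probability
#'   of a mutant with norm \code{m} into residents with norm \code{r}
#'   (diagonal ignored); dimnames, if any, are carried over.
#' @return The 3 x 3 transition matrix \code{W}.
#' @export
transition_matrix <- function(rho) {
  if (!is.matrix(rho) || any(dim(rho) != c(3, 3)))
    stop("rho must be a 3 x 3 matrix", call. = FALSE)
  off <- rho[row(rho) != col(rho)]
  if (any(off < 0 | off > 1 | is.na(off)))
    stop("fixation probabilities must lie in [0, 1]", call. = FALSE)
  W <- t(rho) / 2
  diag(W) <- 0
  diag(W) <- 1 - rowSums(W)
  dimnames(W) <- rev(dimnames(rho))
  W
}

#' Stationary distribution of a small Markov chain
#'
#' Solves \eqn{\pi W = \pi}, \eqn{\sum_i \pi_i = 1} for a row-stochastic
#' matrix by replacing one balance equation with the normalization
#' constraint.  The chain must be irreducible (with all fixation
#' probabilities positive this always holds).
#'
#' @param W a row-stochastic matrix.
#' @return The stationary probability vector.
#' @export
stationary_distribution <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be square", call. = FALSE)
  if (max(abs(rowSums(W) - 1)) > 1e-8)
    stop("W must be row-stochastic", call. = FALSE)
  n <- nrow(W)
  A <- t(diag(n) - W)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- tryCatch(solve(A, b), error = function(e)
    stop("chain appears reducible; cannot solve for a unique stationary ",
         "distribution", call. = FALSE))
  if (any(p < -1e-9))
    stop("chain appears reducible; stationary solve produced negative mass",
         call. = FALSE)
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), rownames(W))
}

#' Equilibrium cooperation rate
#'
#' Weights the average cooperation rate of each homogeneous population by how
#' often that population is visited in the selection-mutation equilibrium.
#'
#' @param stationary stationary distribution over the three homogeneous
#'   populations.
#' @param homogeneous_coop_rates cooperation rate of each homogeneous
#'   population, same order.
#' @return A scalar cooperation rate.
#' @export
equilibrium_cooperation <- function(stationary, homogeneous_coop_rates) {
  if (length(stationary) != length(homogeneous_coop_rates))
    stop("length mismatch", call. = FALSE)
  sum(stationary * homogeneous_coop_rates)
}

#' Run the three-norm evolutionary competition
#'
#' Simulates pairwise payoff profiles for the three unordered pairs of the
#' norm set (each sweep yields both invasion directions), computes the six
#' fixation probabilities, assembles the rare-mutation transition matrix and
#' its stationary distribution, and weights homogeneous cooperation rates by
#' that distribution.  The homogeneous cooperation rate is 1 for ALLC, 0 for
#' ALLD, and simulated for the leading-eight norm.
#'
#' @param config an [evo_config()].
#' @return An \code{evolution_result} with the fixation matrix \code{rho}
#'   (\code{rho[m, r]}: mutant \code{m} into resident \code{r}), transition
#'   matrix \code{W}, \code{stationary} abundances, homogeneous cooperation
#'   rates and the equilibrium \code{coop_rate}.
#' @export
run_evolution <- function(config) {
  stopifnot(inherits(config, "evo_config"))
  nms <- config$norm_names
  rho <- matrix(NA_real_, 3, 3, dimnames = list(mutant = nms, resident = nms))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  profiles <- list()
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    prof <- pairwise_payoffs(config$norm_set[[a]], config$norm_set[[b]],
                             config)
    profiles[[paste(nms[a], nms[b], sep = "_vs_")]] <- prof
    # a-mutant into b-residents: k = number of a-players
    rho[a, b] <- fixation_probability(prof$pi_A, prof$pi_B, config$s)
    # b-mutant into a-residents: k b-players equals composition N - k a-players
    rho[b, a] <- fixation_probability(rev(prof$pi_B), rev(prof$pi_A),
                                      config$s)
  }
  W <- transition_matrix(rho)
  stat <- stationary_distribution(W)
  hom <- numeric(3)
  for (i in 1:3) {
    nm <- config$norm_set[[i]]
    if (nm$name == "ALLC") hom[i] <- 1
    else if (nm$name == "ALLD") hom[i] <- 0
    else {
      cfg <- sim_config(rep(list(nm), config$N), b = config$b, c = config$c,
                        q = config$q, epsilon = config$epsilon,
                        T = config$rep_T,
                        seed = .child_seed(config$seed, 7, i))
      hom[i] <- simulate_reputation(cfg)$coop_rate
    }
  }
  structure(list(rho = rho, W = W, stationary = stat,
                 homogeneous_coop_rates = stats::setNames(hom, nms),
                 coop_rate = equilibrium_cooperation(stat, hom),
                 payoff_profiles = profiles,
                 config = config),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Rare-mutation competition (N = %d, s = %g, b = %g, c = %g, q = %g, eps = %g)\n",
    cfg$N, cfg$s, cfg$b, cfg$c, cfg$q, cfg$epsilon))
  cat("  stationary abundances:\n")
  print(round(x$stationary, 4))
  cat(sprintf("  equilibrium cooperation rate: %.4f\n", x$coop_rate))
  invisible(x)
}
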