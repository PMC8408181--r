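# Reputation dynamics: the round-by-round donation game with private
# observation, the image matrix, and payoffs.

#' Configuration of a reputation simulation
#'
#' Collects the parameters of the donation game with private reputations.
#' Every round a donor and a recipient are drawn uniformly among ordered
#' pairs; the donor cooperates according to its action rule, given its
#' self-image and its image of the recipient.  Each of the remaining
#' \code{N - 1} players independently observes the action with probability
#' \code{q} and misperceives it (C and D flipped) with probability
#' \code{epsilon}; observers then update their private image of the donor via
#' their assessment rule, using their own current images of donor and
#' recipient as context.  The donor updates its own self-image using the true
#' action.
#'
#' @param norms a list of \code{social_norm} objects, one per player; the
#'   population size \code{N} is its length.
#' @param b,c benefit and cost of cooperation, \code{0 < c < b}.
#' @param q per-round observation probability of each non-donor.
#' @param epsilon misperception probability per observation.
#' @param T number of rounds that enter the time averages.
#' @param seed integer seed for the simulation's random stream.
#' @param burn_in rounds simulated before averaging starts (default 0: the
#'   averages include the approach from the all-good initial matrix).
#' @param self_update how the donor maintains its self-image:
#'   \code{"always"} (default), \code{"with_prob_q"} or \code{"never"}.
#' @param recipient_sees whether the recipient observes like any other
#'   player (\code{"like_others"}, default) or \code{"always"}.
#' @return A \code{sim_config} object.
#' @examples
#' cfg <- sim_config(c(rep(list(leading_eight(1)), 2), list(alld())),
#'                   b = 5, c = 1, q = 0.9, epsilon = 0.05, T = 1000)
#' @export
sim_config <- function(norms, b = 5, c = 1, q = 0.9, epsilon = 0.05,
                       T = 2e6, seed = 1, burn_in = 0,
                       self_update = c("always", "with_prob_q", "never"),
                       recipient_sees = c("like_others", "always")) {
  if (!is.list(norms) || length(norms) < 2 ||
      !all(vapply(norms, inherits, TRUE, "social_norm")))
    stop("norms must be a list of at least two social_norm objects",
         call. = FALSE)
  if (!(c > 0 && b > c)) stop("need 0 < c < b", call. = FALSE)
  if (q < 0 || q > 1 || epsilon < 0 || epsilon > 1)
    stop("q and epsilon must lie in [0, 1]", call. = FALSE)
  if (T < 1) stop("T must be at least 1", call. = FALSE)
  if (burn_in < 0) stop("burn_in must be non-negative", call. = FALSE)
  self_update <- match.arg(self_update)
  recipient_sees <- match.arg(recipient_sees)
  structure(list(norms = norms, N = length(norms), b = b, c = c, q = q,
                 epsilon = epsilon, T = as.numeric(T), seed = as.numeric(seed),
                 burn_in = as.numeric(burn_in),
                 self_update = self_update, recipient_sees = recipient_sees),
            class = "sim_config")
}

.norm_matrices <- function(norms) {
  assess <- t(vapply(norms, function(n) unname(n$assessment), numeric(8)))
  act <- t(vapply(norms, function(n) unname(n$action), numeric(4)))
  list(assess = assess, act = act)
}

.self_update_code <- function(x)
  match(x, c("always", "with_prob_q", "never")) - 1L
.recipient_sees_code <- function(x)
  match(x, c("like_others", "always")) - 1L

#' Simulate reputation dynamics
#'
#' Iterates the donation game from an all-good image matrix and summarizes
#' the \code{config$T} rounds that follow the (by default empty) burn-in:
#' the time-averaged image matrix (mean of \eqn{m_{ij}(t)}), the empirical cooperation
#' matrix \eqn{\hat x_{ij}} (cooperations of donor i toward recipient j over
#' their realized interactions; 0 for pairs that never interacted), payoffs
#' \eqn{\pi_i = \frac{1}{N-1}\sum_{j \ne i} (b \hat x_{ji} - c \hat x_{ij})},
#' and the population cooperation rate.  Runs are reproducible given
#' \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @return A \code{reputation_summary} with elements \code{avg_image},
#'   \code{coop_matrix}, \code{interaction_count}, \code{payoffs},
#'   \code{coop_rate}, \code{final_image}, \code{norm_names} and
#'   \code{config}.
#' @examples
#' cfg <- sim_config(rep(list(allc()), 4), T = 500)
#' simulate_reputation(cfg)$coop_rate  # ALLC always cooperates
#' @export
simulate_reputation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nm <- .norm_matrices(config$norms)
  res <- cpp_simulate_reputation(nm$assess, nm$act, config$T, config$q,
                                 config$epsilon,
                                 .self_update_code(config$self_update),
                                 .recipient_sees_code(config$recipient_sees),
                                 config$seed, config$burn_in)
  coop_matrix <- res$coop_count / pmax(res$interaction_count, 1)
  payoffs <- payoffs_from_coop(coop_matrix, config$b, config$c)
  structure(list(avg_image = res$avg_image,
                 coop_matrix = coop_matrix,
                 interaction_count = res$interaction_count,
                 payoffs = payoffs,
                 coop_rate = res$coop_rate,
                 final_image = res$final_image,
                 norm_names = vapply(config$norms, `[[`, "", "name"),
                 config = config),
            class = "reputation_summary")
}

#' Payoffs from a cooperation matrix
#'
#' Evaluates \eqn{\pi_i = \frac{1}{N-1} \sum_{j \ne i}
#' (b \hat x_{ji} - c \hat x_{ij})}: each player receives \code{b} times the
#' rate at which others cooperate with it and pays \code{c} times the rate at
#' which it cooperates with others.  The diagonal is ignored.
#'
#' @param coop_matrix square matrix of pairwise cooperation frequencies,
#'   rows = donors, columns = recipients, entries between 0 and 1.
#' @param b,c benefit and cost of cooperation.
#' @return A numeric payoff vector of length \code{nrow(coop_matrix)}.
#' @examples
#' payoffs_from_coop(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE), b = 5, c = 1)
#' @export
payoffs_from_coop <- function(coop_matrix, b, c) {
  if (!is.matrix(coop_matrix) || nrow(coop_matrix) != ncol(coop_matrix))
    stop("coop_matrix must be a square matrix", call. = FALSE)
  n <- nrow(coop_matrix)
  d <- diag(coop_matrix)
  (b * (colSums(coop_matrix) - d) - c * (rowSums(coop_matrix) - d)) / (n - 1)
}

#' Advance the image matrix by a single round
#'
#' Pure-R reference implementation of one round of the reputation dynamics,
#' driven by R's random number stream (use \code{set.seed()} for
#' reproducibility).  The draw order within the round is: donor, recipient,
#' action, then per observer in player order (observe?, misperceive?,
#' assessment), then the donor's self-update.  All reputation contexts are
#' read from the image matrix as it stood at the start of the round.
#'
#' @param M binary \code{N x N} image matrix; \code{M[i, j] = 1} means player
#'   \code{i} regards player \code{j} as good.
#' @param config a [sim_config()] (its \code{T} and \code{seed} are ignored).
#' @return A list with the updated matrix \code{M} and \code{record}, a list
#'   holding \code{donor}, \code{recipient} and \code{action} ("C" or "D").
#' @export
reputation_step <- function(M, config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  if (!is.matrix(M) || nrow(M) != N || ncol(M) != N || !all(M %in% c(0, 1)))
    stop("M must be a binary N x N matrix matching the config", call. = FALSE)
  M0 <- M
  lab <- function(v) if (v == 1) "G" else "B"
  donor <- min(floor(stats::runif(1) * N) + 1, N)
  r <- min(floor(stats::runif(1) * (N - 1)) + 1, N - 1)
  recip <- if (r >= donor) r + 1 else r
  p_coop <- action_prob(config$norms[[donor]],
                        lab(M0[donor, donor]), lab(M0[donor, recip]))
  action <- if (stats::runif(1) < p_coop) "C" else "D"
  for (o in seq_len(N)) {
    if (o == donor) next
    observes <- if (config$recipient_sees == "always" && o == recip) TRUE
                else stats::runif(1) < config$q
    if (!observes) next
    perceived <- action
    if (stats::runif(1) < config$epsilon)
      perceived <- if (action == "C") "D" else "C"
    p_good <- assessment_prob(config$norms[[o]], perceived,
                              lab(M0[o, donor]), lab(M0[o, recip]))
    M[o, donor] <- as.integer(stats::runif(1) < p_good)
  }
  do_self <- switch(config$self_update,
                    always = TRUE,
                    with_prob_q = stats::runif(1) < config$q,
                    never = FALSE)
  if (do_self) {
    p_good <- assessment_prob(config$norms[[donor]], action,
                              lab(M0[donor, donor]), lab(M0[donor, recip]))
    M[donor, donor] <- as.integer(stats::runif(1) < p_good)
  }
  list(M = M, record = list(donor = donor, recipient = recip, action = action))
}

#' Exact long-run image distribution for tiny populations
#'
#' For \code{N <= 3} the image-matrix process is a Markov chain on the
#' \code{2^(N^2)} binary matrices.  This function builds the exact one-round
#' transition matrix by enumerating donor-recipient pairs, action outcomes
#' and all observation / misperception / assessment outcomes with their
#' probabilities.  It returns both the limiting distribution reached from
#' the all-good initial state (computed by repeated squaring of the
#' transition matrix) and the exact expectation of the time averages that
#' [simulate_reputation()] estimates: the mean of the state distribution
#' over rounds \code{burn_in + 1, ..., burn_in + T}.  It serves as an
#' independent oracle for the simulator.
#'
#' @param config a [sim_config()] with \code{N <= 3} (\code{seed} is
#'   ignored; \code{T} and \code{burn_in} define the averaging window).
#' @return A list with \code{distribution} (the limiting distribution over
#'   states; state \code{s} encodes entry \code{(i, j)} in bit
#'   \code{(i - 1) * N + j - 1}), \code{avg_distribution} (expected time
#'   average over the config's window), \code{image_expectation} (the
#'   \code{N x N} matrix of expected time-averaged images, comparable to the
#'   simulator's \code{avg_image}) and the transition matrix \code{W}.
#' @export
exact_stationary_small <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  if (N > 3)
    stop("exact enumeration is limited to N <= 3", call. = FALSE)
  S <- 2^(N * N)
  nm <- .norm_matrices(config$norms)
  q <- config$q; eps <- config$epsilon
  aidx <- function(coop, dg, rg)
    (if (coop) 0L else 4L) + (if (dg) 0L else 2L) + (if (rg) 0L else 1L) + 1L
  bidx <- function(sg, rg) (if (sg) 0L else 2L) + (if (rg) 0L else 1L) + 1L
  decode <- function(s) {
    bits <- as.integer(intToBits(s))[seq_len(N * N)]
    matrix(bits, N, N, byrow = TRUE)
  }
  bitpos <- function(i, j) (i - 1L) * N + (j - 1L)
  W <- matrix(0, S, S)
  p_pair <- 1 / (N * (N - 1))
  for (s in 0:(S - 1)) {
    m <- decode(s)
    for (donor in 1:N) for (recip in setdiff(1:N, donor)) {
      pC <- nm$act[donor, bidx(m[donor, donor] == 1, m[donor, recip] == 1)]
      for (coop in c(1L, 0L)) {
        pa <- if (coop == 1L) pC else 1 - pC
        if (pa == 0) next
        ent <- integer(0); p1 <- numeric(0)
        for (o in setdiff(1:N, donor)) {
          p_obs <- if (config$recipient_sees == "always" && o == recip) 1 else q
          cur <- m[o, donor]
          a_same <- nm$assess[o, aidx(coop == 1L, m[o, donor] == 1,
                                      m[o, recip] == 1)]
          a_flip <- nm$assess[o, aidx(coop != 1L, m[o, donor] == 1,
                                      m[o, recip] == 1)]
          ent <- c(ent, bitpos(o, donor))
          p1 <- c(p1, (1 - p_obs) * cur +
                        p_obs * ((1 - eps) * a_same + eps * a_flip))
        }
        p_self_upd <- switch(config$self_update,
                             always = 1, with_prob_q = q, never = 0)
        if (p_self_upd > 0) {
          a_self <- nm$assess[donor, aidx(coop == 1L, m[donor, donor] == 1,
                                          m[donor, recip] == 1)]
          ent <- c(ent, bitpos(donor, donor))
          p1 <- c(p1, (1 - p_self_upd) * m[donor, donor] + p_self_upd * a_self)
        }
        K <- length(ent)
        base <- s
        for (e in seq_len(K))
          base <- bitwAnd(base, bitwNot(bitwShiftL(1L, ent[e])))
        for (combo in 0:(2^K - 1)) {
          cb <- as.integer(intToBits(combo))[seq_len(K)]
          prob <- prod(ifelse(cb == 1L, p1, 1 - p1))
          if (prob == 0) next
          tgt <- base
          for (e in seq_len(K)) if (cb[e] == 1L)
            tgt <- bitwOr(tgt, bitwShiftL(1L, ent[e]))
          W[s + 1, tgt + 1] <- W[s + 1, tgt + 1] + p_pair * pa * prob
        }
      }
    }
  }
  v <- numeric(S); v[S] <- 1  # all-good start
  B <- W
  prev <- as.numeric(v %*% B)
  for (k in 1:45) {
    B <- B %*% B
    B <- B / rowSums(B)  # guard against numerical drift
    cur <- as.numeric(v %*% B)
    if (max(abs(cur - prev)) < 1e-14) break
    prev <- cur
  }
  vB <- v %*% B
  dist <- as.numeric(0.5 * (vB + vB %*% W))
  dist <- pmax(dist, 0); dist <- dist / sum(dist)

  # expected time average over rounds burn_in + 1 .. burn_in + T: iterate the
  # distribution round by round until it stops moving, then add the settled
  # tail in one step
  total <- config$burn_in + config$T
  d <- v
  avg <- numeric(S)
  counted <- 0
  for (t in seq_len(total)) {
    d_new <- as.numeric(d %*% W)
    if (t > config$burn_in) {
      avg <- avg + d_new
      counted <- counted + 1
    }
    if (max(abs(d_new - d)) < 1e-14) {
      avg <- avg + (config$T - counted) * d_new
      counted <- config$T
      break
    }
    d <- d_new
  }
  avg <- avg / config$T

  img <- matrix(0, N, N)
  for (s in 0:(S - 1)) {
    if (avg[s + 1] == 0) next
    img <- img + avg[s + 1] * decode(s)
  }
  list(distribution = dist, avg_distribution = avg,
       image_expectation = img, W = W)
}

#' @export
print.reputation_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Reputation dynamics: N = %d, T = %g, b = %g, c = %g, q = %g, eps = %g\n",
    cfg$N, cfg$T, cfg$b, cfg$c, cfg$q, cfg$epsilon))
  tab <- table(x$norm_names)
  cat("  norms:", paste(sprintf("%s x %d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  population cooperation rate: %.4f\n", x$coop_rate))
  groups <- x$norm_names
  blocks <- block_average(x$avg_image, groups)
  cat("  mean image (observer group -> target group, diagonal excluded):\n")
  print(round(blocks, 4))
  invisible(x)
}

#' @export
summary.reputation_summary <- function(object, ...) {
  groups <- object$norm_names
  list(coop_rate = object$coop_rate,
       image_blocks = block_average(object$avg_image, groups),
       coop_blocks = block_average(object$coop_matrix, groups),
       mean_payoff_by_norm = tapply(object$payoffs, groups, mean))
}

#' Plot a time-averaged image matrix
#'
#' Displays the \code{avg_image} matrix of a simulation as a grey-scale
#' raster, observers in rows (white = regarded as good throughout).
#'
#' @param x a \code{reputation_summary}.
#' @param ... passed on to [graphics::image()].
#' @export
plot.reputation_summary <- function(x, ...) {
  N <- nrow(x$avg_image)
  graphics::image(seq_len(N), seq_len(N),
                  t(x$avg_image[N:1, , drop = FALSE]),
                  zlim = c(0, 1), col = grDevices::grey.colors(64, 0, 1),
                  xlab = "target player", ylab = "observer",
                  axes = FALSE, ...)
  graphics::box()
  invisible(x)
}
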