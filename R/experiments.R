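# Config-driven reproduction of the study scenarios: mixed-population
# reputation dynamics (thirds of a leading-eight norm, ALLC and ALLD),
# rare-mutation competitions across generosity scenarios, and generosity
# grids.  All outputs are plain CSV plus a JSON sidecar carrying the full
# configuration and seed, so every file is reproducible on its own.

#' Block averages of an image matrix
#'
#' Averages the entries of \code{avg_image} over each pair of player groups
#' (observer group in rows, target group in columns), excluding the diagonal
#' self-image entries.
#'
#' @param avg_image square numeric matrix.
#' @param groups vector of group labels, one per player.
#' @return A matrix of block means with one row/column per group (in order of
#'   first appearance).
#' @examples
#' block_average(diag(4), rep(c("a", "b"), each = 2))
#' @export
block_average <- function(avg_image, groups) {
  if (!is.matrix(avg_image) || nrow(avg_image) != ncol(avg_image))
    stop("avg_image must be square", call. = FALSE)
  if (length(groups) != nrow(avg_image))
    stop("groups must label every player", call. = FALSE)
  labs <- unique(groups)
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(observer = labs, target = labs))
  off <- row(avg_image) != col(avg_image)
  for (a in labs) for (b in labs) {
    sel <- outer(groups == a, groups == b) & off
    out[a, b] <- mean(avg_image[sel])
  }
  out
}

# the four generosity scenarios used throughout the evolutionary analyses
.GENEROSITY_SCENARIOS <- list(
  baseline = c(g1 = 0, g2 = 0),
  assessment = c(g1 = 0.05, g2 = 0),
  action = c(g1 = 0, g2 = 0.05),
  both = c(g1 = 0.05, g2 = 0.05)
)

.thirds_population <- function(norm, N = 90) {
  stopifnot(N %% 3 == 0)
  c(rep(list(norm), N / 3), rep(list(allc()), N / 3),
    rep(list(alld()), N / 3))
}

#' Run a predefined experiment
#'
#' Reproduces one of the study's figure-level experiments, optionally at
#' reduced scale.  \code{"fig2"} and \code{"fig3"} run the mixed-population
#' reputation dynamics (N = 90, equal thirds of a leading-eight norm, ALLC
#' and ALLD; T = 2e6 rounds) under the four information/generosity
#' scenarios, with assessment generosity (fig2) or action generosity (fig3).
#' \code{"fig4"} runs the rare-mutation competition (N = 50, b = 5, c = 1,
#' q = 0.9, epsilon = 0.05, s = 1, 1e6 rounds per composition) for the four
#' generosity scenarios.  \code{"fig5"} sweeps a g1 x g2 grid (steps of 0.05
#' up to 0.5) and records equilibrium cooperation; \code{"fig6"} repeats the
#' four generosity scenarios while varying epsilon, b or q.  \code{scale}
#' multiplies all simulated round counts and thins sweep grids, preserving
#' the structure of the outputs at a fraction of the cost.
#'
#' @param figure one of \code{"fig2"}, \code{"fig3"}, \code{"fig4"},
#'   \code{"fig5"}, \code{"fig6"}.
#' @param norms leading-eight indices to include (default depends on the
#'   figure: 1 and 7 for fig2-fig4, all eight for fig5 and fig6).
#' @param scale factor in (0, 1] applied to simulation lengths and grid
#'   resolution.
#' @param seed master seed; each scenario derives an independent child seed.
#' @param out_dir directory for CSV/JSON output, created if needed; use
#'   \code{NULL} to skip writing.
#' @param vary for fig6: which parameter to sweep (\code{"epsilon"},
#'   \code{"b"} or \code{"q"}).
#' @return Invisibly, a list of result data frames (also written to
#'   \code{out_dir}).
#' @export
run_experiment <- function(figure = c("fig2", "fig3", "fig4", "fig5", "fig6"),
                           norms = NULL, scale = 1, seed = 1, out_dir = NULL,
                           vary = c("epsilon", "b", "q")) {
  figure <- match.arg(figure)
  vary <- match.arg(vary)
  if (!(scale > 0 && scale <= 1))
    stop("scale must lie in (0, 1]", call. = FALSE)
  if (is.null(norms))
    norms <- if (figure %in% c("fig2", "fig3", "fig4")) c(1, 7) else 1:8
  fig_id <- match(figure, c("fig2", "fig3", "fig4", "fig5", "fig6"))
  results <- switch(figure,
    fig2 = .exp_reputation(norms, g_kind = "g1", scale, seed, fig_id),
    fig3 = .exp_reputation(norms, g_kind = "g2", scale, seed, fig_id),
    fig4 = .exp_evolution(norms, scale, seed, fig_id),
    fig5 = .exp_grid(norms, scale, seed, fig_id),
    fig6 = .exp_vary(norms, vary, scale, seed, fig_id))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      utils::write.csv(results[[nm]],
                       file.path(out_dir, paste0(figure, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    meta <- list(figure = figure, norms = norms, scale = scale, seed = seed,
                 vary = if (figure == "fig6") vary else NULL,
                 generated = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(meta, file.path(out_dir, paste0(figure, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}

# mixed-population reputation dynamics under the four information/generosity
# scenarios of the image-matrix figures
.exp_reputation <- function(norms, g_kind, scale, seed, fig_id) {
  T_rounds <- max(1, round(2e6 * scale))
  scen <- expand.grid(noisy = c(FALSE, TRUE), generous = c(FALSE, TRUE))
  rows <- list()
  for (idx in norms) {
    for (s in seq_len(nrow(scen))) {
      g <- if (scen$generous[s]) 0.05 else 0
      L <- if (g_kind == "g1") make_generous(leading_eight(idx), g, 0)
           else make_generous(leading_eight(idx), 0, g)
      eps <- if (scen$noisy[s]) 0.05 else 0
      q <- if (scen$noisy[s]) 0.9 else 1
      cfg <- sim_config(.thirds_population(L), b = 5, c = 1, q = q,
                        epsilon = eps, T = T_rounds,
                        seed = .child_seed(seed, fig_id, idx, s))
      sim <- simulate_reputation(cfg)
      blocks <- block_average(sim$avg_image, sim$norm_names)
      for (a in rownames(blocks)) for (b in colnames(blocks)) {
        rows[[length(rows) + 1]] <- data.frame(
          norm = paste0("L", idx), noisy = scen$noisy[s], g = g,
          g_kind = g_kind, observer = a, target = b,
          mean_image = blocks[a, b], coop_rate = sim$coop_rate,
          T = T_rounds, seed = cfg$seed)
      }
    }
  }
  list(image_blocks = do.call(rbind, rows))
}

# rare-mutation competitions for the four generosity scenarios
.exp_evolution <- function(norms, scale, seed, fig_id, b = 5, q = 0.9,
                           epsilon = 0.05) {
  rep_T <- max(1000, round(1e6 * scale))
  rows <- list()
  for (idx in norms) {
    for (s in seq_along(.GENEROSITY_SCENARIOS)) {
      g <- .GENEROSITY_SCENARIOS[[s]]
      L <- make_generous(leading_eight(idx), g[["g1"]], g[["g2"]])
      cfg <- evo_config(list(L, allc(), alld()), N = 50, s = 1, b = b, c = 1,
                        q = q, epsilon = epsilon, rep_T = rep_T,
                        seed = .child_seed(seed, fig_id, idx, s))
      ev <- run_evolution(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        norm = paste0("L", idx), scenario = names(.GENEROSITY_SCENARIOS)[s],
        g1 = g[["g1"]], g2 = g[["g2"]],
        abundance_L = unname(ev$stationary[1]),
        abundance_ALLC = unname(ev$stationary[2]),
        abundance_ALLD = unname(ev$stationary[3]),
        coop_rate = ev$coop_rate, rep_T = rep_T, seed = cfg$seed)
    }
  }
  list(abundances = do.call(rbind, rows))
}

# g1 x g2 grid of equilibrium cooperation rates
.exp_grid <- function(norms, scale, seed, fig_id) {
  rep_T <- max(1000, round(1e6 * scale))
  step <- if (scale >= 1) 0.05 else 0.05 * ceiling(1 / sqrt(scale))
  gvals <- unique(c(seq(0, 0.5, by = step), 0.5))
  rows <- list()
  for (idx in norms) {
    for (g1 in gvals) for (g2 in gvals) {
      L <- make_generous(leading_eight(idx), g1, g2)
      cfg <- evo_config(list(L, allc(), alld()), N = 50, s = 1, b = 5, c = 1,
                        q = 0.9, epsilon = 0.05, rep_T = rep_T,
                        seed = .child_seed(seed, fig_id, idx,
                                           round(1000 * g1),
                                           round(1000 * g2)))
      ev <- run_evolution(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        norm = paste0("L", idx), g1 = g1, g2 = g2,
        abundance_L = unname(ev$stationary[1]),
        coop_rate = ev$coop_rate, rep_T = rep_T, seed = cfg$seed)
    }
  }
  list(coop_grid = do.call(rbind, rows))
}

# parameter sweeps of the four generosity scenarios
.exp_vary <- function(norms, vary, scale, seed, fig_id) {
  grid <- switch(vary,
                 epsilon = seq(0, 0.3, by = 0.05),
                 b = c(1.5, 2, 3, 4, 5, 7, 10),
                 q = seq(0.3, 1, by = 0.1))
  if (scale < 1)
    grid <- grid[unique(round(seq(1, length(grid),
                                  length.out = max(2, ceiling(length(grid) * sqrt(scale))))))]
  rows <- list()
  for (idx in norms) {
    for (s in seq_along(.GENEROSITY_SCENARIOS)) {
      for (v in grid) {
        b <- if (vary == "b") v else 5
        q <- if (vary == "q") v else 0.9
        epsilon <- if (vary == "epsilon") v else 0.05
        g <- .GENEROSITY_SCENARIOS[[s]]
        L <- make_generous(leading_eight(idx), g[["g1"]], g[["g2"]])
        rep_T <- max(1000, round(1e6 * scale))
        cfg <- evo_config(list(L, allc(), alld()), N = 50, s = 1, b = b,
                          c = 1, q = q, epsilon = epsilon, rep_T = rep_T,
                          seed = .child_seed(seed, fig_id, idx, s,
                                             round(1000 * v)))
        ev <- run_evolution(cfg)
        rows[[length(rows) + 1]] <- data.frame(
          norm = paste0("L", idx),
          scenario = names(.GENEROSITY_SCENARIOS)[s],
          vary = vary, value = v, coop_rate = ev$coop_rate,
          abundance_L = unname(ev$stationary[1]), rep_T = rep_T,
          seed = cfg$seed)
      }
    }
  }
  list(coop_sweep = do.call(rbind, rows))
}
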