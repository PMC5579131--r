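#' Linear in-silico matching experiment
#'
#' End-to-end run on a seeded random conservative linear network: draw a
#' tracked multivariate-normal cohort, propagate it by the matrix
#' exponential over one interval, scan every species subset for slow
#' variables, then match cells on each class's minimum-JSD subset and score
#' the matching against the (known) identity ground truth.
#'
#' @param n_species number of species (default 14).
#' @param n_cells cells (default 3000).
#' @param times the two measurement times.
#' @param density linear-network sparsity.
#' @param invariant invariant used for the per-class matchings (`"IM"` or
#'   `"IT"`).
#' @param seed integer seed.
#' @param config an [analysis_config()].
#' @return An `experiment_report` list: `scan`, `ranks` (per-class winners),
#'   `evaluations` (one [evaluate_matching()] per class), `chi_ratios`,
#'   `delta_A_ratios`, `network`, `config`.
#' @export
run_linear_experiment <- function(n_species = 14L, n_cells = 3000L,
                                  times = c(0, 7), density = 0.3,
                                  invariant = c("IM", "IT"), seed = 1L,
                                  config = analysis_config()) {
  invariant <- match.arg(invariant)
  net <- make_linear_network(n_species, density = density,
                             conservative = TRUE, seed = seed)
  sim <- generate_snapshot_series(net, n_cells = n_cells, times = times,
                                  mode = "tracked", seed = seed)
  s1 <- sim$series$snapshots[[1L]]
  s2 <- sim$series$snapshots[[2L]]
  scan <- scan_subsets(s1, s2, config = config)
  ranks <- rank_subsets(scan, invariant)
  truth <- sim$ground_truth[[1L]]$partner_abundances
  subsets <- attr(ranks, "subsets")
  evals <- vector("list", nrow(ranks))
  for (i in seq_len(nrow(ranks))) {
    idx <- subsets[[i]]
    if (anyNA(idx)) next
    m <- match_cells(s1, s2, method = invariant, subset = idx,
                     config = config)
    evals[[i]] <- evaluate_matching(m, s1, truth, s2, subset = idx,
                                    n_random = config$n_random,
                                    seed = config$seed)
  }
  structure(list(kind = "linear", scan = scan, ranks = ranks,
                 evaluations = evals,
                 chi_ratios = vapply(evals, function(e)
                   if (is.null(e)) NA_real_ else e$chi_ratio, numeric(1)),
                 delta_A_ratios = vapply(evals, function(e)
                   if (is.null(e)) NA_real_ else e$delta_A_ratio, numeric(1)),
                 network = net, times = times, n_cells = n_cells,
                 invariant = invariant, seed = seed, config = config),
            class = "experiment_report")
}

#' Ras-network synthetic cytometry experiment
#'
#' Batch-mode snapshots of the Ras activation model (an independent cohort
#' per time point, as in flow cytometry), restricted to the six canonically
#' recorded species, scanned for slow I_T subsets; cells are then matched on
#' each class's minimum-JSD(I_T) subset and scored by the relative error
#' against the forward-simulated ground truth.
#'
#' @param preset Ras parameter preset.
#' @param n_cells cells per batch (default 2000).
#' @param times measurement times; the first interval is evaluated.
#' @param record recorded species (default the six canonical ones).
#' @param method `"ssa"` (default) or `"ode"`.
#' @param seed integer seed.
#' @param config an [analysis_config()].
#' @return An `experiment_report` with `scan`, `ranks`, `evaluations`
#'   and `chi_rel_ratios` per class.
#' @export
run_ras_experiment <- function(preset = "bistable", n_cells = 2000L,
                               times = c(0, 100),
                               record = c("RasGTP", "RasGDP", "SOS",
                                          "RasGRP1", "DAG", "RasGAP"),
                               method = c("ssa", "ode"), seed = 1L,
                               config = analysis_config()) {
  method <- match.arg(method)
  net <- build_ras_network(preset)
  sim <- generate_snapshot_series(net, n_cells = n_cells, times = times,
                                  mode = "batch", method = method,
                                  record = record, seed = seed)
  s1 <- sim$series$snapshots[[1L]]
  s2 <- sim$series$snapshots[[2L]]
  scan <- scan_subsets(s1, s2, invariant = "IT", config = config)
  ranks <- rank_subsets(scan, "IT")
  truth_full <- sim$ground_truth[[1L]]$partner_abundances
  truth <- truth_full[, sim$recorded, drop = FALSE]
  subsets <- attr(ranks, "subsets")
  evals <- vector("list", nrow(ranks))
  for (i in seq_len(nrow(ranks))) {
    idx <- subsets[[i]]
    if (anyNA(idx)) next
    m <- match_cells(s1, s2, method = "IT", subset = idx, config = config)
    evals[[i]] <- evaluate_matching(m, s1, truth, s2, subset = idx,
                                    n_random = config$n_random,
                                    seed = config$seed)
  }
  structure(list(kind = "ras", scan = scan, ranks = ranks,
                 evaluations = evals,
                 chi_rel_ratios = vapply(evals, function(e)
                   if (is.null(e)) NA_real_ else e$chi_rel_ratio, numeric(1)),
                 network = net, times = times, n_cells = n_cells,
                 invariant = "IT", seed = seed, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s experiment, %d cells, t = %g vs %g, invariant %s\n",
              x$kind, x$n_cells, x$times[1], x$times[2], x$invariant))
  print(x$ranks, digits = 4)
  if (!is.null(x$chi_ratios))
    cat("chi ratios vs random:", paste(signif(x$chi_ratios, 3),
                                       collapse = ", "), "\n")
  if (!is.null(x$chi_rel_ratios))
    cat("chi_rel ratios vs random:", paste(signif(x$chi_rel_ratios, 3),
                                           collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct trajectories across a snapshot series
#'
#' Matches each pair of successive snapshots on the configured invariant and
#' subset, and chains the pairwise bijections into trajectories. When the
#' series carries hidden ground truth from [strip_identities()], each
#' interval's matching is additionally evaluated (per-cell errors and
#' correlation-matrix error against the random baseline).
#'
#' @param series a [snapshot_series] with at least two snapshots and equal
#'   cell counts (see [downsample_to_match()]).
#' @param invariant `"IT"` or `"IM"`.
#' @param subset species subset used for the invariant (default full panel).
#' @param config an [analysis_config()].
#' @return A list of class `reconstruction`: `matchings` (per interval),
#'   `trajectories` (N x T matrix of row indices into each snapshot),
#'   `evaluations` (per interval, when ground truth is available),
#'   `delta_A_ratios`, `chi_means`.
#' @export
run_reconstruction <- function(series, invariant = c("IT", "IM"),
                               subset = NULL, config = analysis_config()) {
  invariant <- match.arg(invariant)
  stopifnot(inherits(series, "snapshot_series"))
  snaps <- series$snapshots
  nt <- length(snaps)
  if (nt < 2L) stop("need at least two snapshots")
  sizes <- vapply(snaps, n_cells, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("unequal cell counts across snapshots; use downsample_to_match()")
  N <- sizes[1L]
  perms <- series$metadata$anonymised_perms
  matchings <- vector("list", nt - 1L)
  evals <- vector("list", nt - 1L)
  for (i in seq_len(nt - 1L)) {
    m <- match_cells(snaps[[i]], snaps[[i + 1L]], method = invariant,
                     subset = subset, config = config)
    matchings[[i]] <- m
    if (!is.null(perms)) {
      # row r of snapshot i is original cell perms[[i]][r]; its correct
      # partner is the row of snapshot i+1 holding the same original cell
      correct_row <- match(perms[[i]], perms[[i + 1L]])
      truth <- snaps[[i + 1L]]$abundances[correct_row, , drop = FALSE]
      evals[[i]] <- evaluate_matching(m, snaps[[i]], truth, snaps[[i + 1L]],
                                      subset = subset,
                                      n_random = config$n_random,
                                      seed = config$seed)
    }
  }
  traj <- matrix(NA_integer_, N, nt)
  traj[, 1L] <- seq_len(N)
  for (i in seq_len(nt - 1L))
    traj[, i + 1L] <- matchings[[i]]$perm[traj[, i]]
  structure(list(matchings = matchings, trajectories = traj,
                 evaluations = evals,
                 chi_means = vapply(evals, function(e)
                   if (is.null(e)) NA_real_ else e$chi_mean, numeric(1)),
                 delta_A_ratios = vapply(evals, function(e)
                   if (is.null(e)) NA_real_ else e$delta_A_ratio, numeric(1)),
                 invariant = invariant, subset = subset),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d interval(s), invariant %s\n",
              length(x$matchings), x$invariant))
  if (any(!is.na(x$delta_A_ratios)))
    cat(sprintf("  delta_A/random < 1 in %d of %d intervals\n",
                sum(x$delta_A_ratios < 1, na.rm = TRUE),
                sum(!is.na(x$delta_A_ratios))))
  invisible(x)
}
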