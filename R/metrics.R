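#' Per-cell matching error chi
#'
#' For each t1 cell, the Euclidean distance (in the space of the evaluation
#' subset's species) between the abundances of its assigned sister cell and
#' of its correct partner at t2. Zero exactly where the sister is the correct
#' partner. Set `squared = TRUE` for the squared-distance variant; orderings
#' and zero-sets are identical either way.
#'
#' @param sister N x k matrix: row a holds the sister cell's abundances for
#'   t1 cell a (i.e. already aligned through the matching).
#' @param correct N x k matrix: row a holds the correct partner's abundances.
#' @param squared report squared distances instead of distances.
#' @return Numeric vector of length N.
#' @export
chi_errors <- function(sister, correct, squared = FALSE) {
  sister <- as.matrix(sister); correct <- as.matrix(correct)
  if (!identical(dim(sister), dim(correct)))
    stop("'sister' and 'correct' must have the same dimensions")
  ss <- rowSums((sister - correct)^2)
  if (squared) ss else sqrt(ss)
}

#' Per-cell relative matching error
#'
#' Scale-free variant of [chi_errors()] used to compare subsets whose species
#' abundances live on very different scales: per cell, the sum over subset
#' species of |sister - correct| / |correct|. Species terms with a zero
#' correct-partner abundance are skipped (their count is reported); cells
#' whose every term is skipped get NA and are excluded from means.
#'
#' @inheritParams chi_errors
#' @return Numeric vector of length N with attributes `skipped_terms` (total
#'   skipped species terms) and `undefined_cells` (cells with all terms
#'   skipped).
#' @export
chi_relative <- function(sister, correct) {
  sister <- as.matrix(sister); correct <- as.matrix(correct)
  if (!identical(dim(sister), dim(correct)))
    stop("'sister' and 'correct' must have the same dimensions")
  ok <- correct != 0
  rel <- abs(sister - correct) / abs(correct)
  rel[!ok] <- 0
  out <- rowSums(rel)
  none <- rowSums(ok) == 0L
  out[none] <- NA_real_
  attr(out, "skipped_terms") <- sum(!ok)
  attr(out, "undefined_cells") <- sum(none)
  out
}

#' Cross-time correlation matrix of a pairing
#'
#' Centred cross-covariance between species i at t1 and species j at t2
#' under a given pairing, with the biased 1/N normalisation and means taken
#' over each snapshot's full population. With identical inputs and the
#' identity pairing this reduces to the population covariance.
#'
#' @param x1 N x k abundances at t1.
#' @param x2_partner N x k abundances at t2, row-aligned to `x1` via the
#'   pairing under evaluation.
#' @param mu1,mu2 optional population means (default: column means of the
#'   supplied matrices).
#' @return k x k matrix.
#' @export
cross_correlation <- function(x1, x2_partner, mu1 = NULL, mu2 = NULL) {
  x1 <- as.matrix(x1); x2_partner <- as.matrix(x2_partner)
  N <- nrow(x1)
  if (N < 2L) stop("need at least 2 cells")
  if (nrow(x2_partner) != N) stop("row counts differ")
  if (is.null(mu1)) mu1 <- colMeans(x1)
  if (is.null(mu2)) mu2 <- colMeans(x2_partner)
  crossprod(sweep(x1, 2L, mu1), sweep(x2_partner, 2L, mu2)) / N
}

#' Squared distance between two correlation matrices
#'
#' Sum of squared entrywise differences (no square root), the discrepancy
#' between the cross-time correlation under the evaluated pairing and under
#' the correct pairing.
#'
#' @param A_correct,A_sister matrices of identical shape.
#' @return Non-negative number; 0 iff the matrices are equal.
#' @export
delta_A <- function(A_correct, A_sister) {
  A_correct <- as.matrix(A_correct); A_sister <- as.matrix(A_sister)
  if (!identical(dim(A_correct), dim(A_sister))) stop("shape mismatch")
  sum((A_correct - A_sister)^2)
}

#' Evaluate a matching against ground truth
#'
#' Computes the per-cell errors (chi and its relative variant), the
#' cross-time correlation matrices under the evaluated and the correct
#' pairing, their discrepancy delta_A, and the ratios of these errors to a
#' random-pairing baseline averaged over R seeded random permutations.
#'
#' @param matching a `cell_matching` (its `perm` maps t1 rows to t2 rows).
#' @param snap1 the t1 [snapshot] (rows = cells alpha).
#' @param truth N x k matrix of correct-partner abundances at t2, row-aligned
#'   to `snap1` (e.g. `ground_truth$partner_abundances` from
#'   [generate_snapshot_series()], restricted to the evaluation subset), or
#'   the t2 [snapshot] itself when the correct pairing is the identity.
#' @param snap2 the t2 [snapshot] supplying sister abundances.
#' @param subset species names or indices used for the evaluation (defaults
#'   to the full panel of `snap1`).
#' @param n_random number of random permutations R for the baseline.
#' @param seed seed for the baseline permutations.
#' @param squared_chi report chi as squared distance.
#' @return An object of class `match_evaluation`: per-cell `chi`, `chi_rel`,
#'   their means, `A_sister`, `A_correct`, `delta_A`, baseline means
#'   `chi_random_mean`, `chi_rel_random_mean`, `delta_A_random_mean` with
#'   Monte-Carlo standard errors, and the ratios `chi_ratio`,
#'   `chi_rel_ratio`, `delta_A_ratio`.
#' @export
evaluate_matching <- function(matching, snap1, truth, snap2, subset = NULL,
                              n_random = 100L, seed = 1L,
                              squared_chi = FALSE) {
  stopifnot(inherits(matching, "cell_matching"))
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("'n_random' must be at least 1")
  if (is.null(subset)) subset <- seq_along(snap1$species)
  idx <- subset_indices(snap1$species, subset)
  X1 <- snap1$abundances[, idx, drop = FALSE]
  X2 <- snap2$abundances[, idx, drop = FALSE]
  if (inherits(truth, "snapshot")) {
    truthX <- truth$abundances[, idx, drop = FALSE]
  } else {
    truth <- as.matrix(truth)
    truthX <- if (ncol(truth) == length(snap1$species))
      truth[, idx, drop = FALSE] else truth
  }
  N <- nrow(X1)
  if (length(matching$perm) != N || nrow(truthX) != N || nrow(X2) != N)
    stop("matching, snapshots and ground truth disagree on cell count")

  sister <- X2[matching$perm, , drop = FALSE]
  chi <- chi_errors(sister, truthX, squared = squared_chi)
  chi_rel <- chi_relative(sister, truthX)

  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  A_sister <- cross_correlation(X1, sister, mu1, mu2)
  A_correct <- cross_correlation(X1, truthX, mu1, colMeans(truthX))
  dimnames(A_correct) <- dimnames(A_sister)
  dA <- delta_A(A_correct, A_sister)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  chi_r <- numeric(n_random); chir_r <- numeric(n_random)
  dA_r <- numeric(n_random)
  for (r in seq_len(n_random)) {
    p <- sample.int(N)
    sr <- X2[p, , drop = FALSE]
    chi_r[r] <- mean(chi_errors(sr, truthX, squared = squared_chi))
    chir_r[r] <- mean(chi_relative(sr, truthX), na.rm = TRUE)
    dA_r[r] <- delta_A(A_correct, cross_correlation(X1, sr, mu1, mu2))
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))

  structure(list(
    chi = chi, chi_rel = chi_rel,
    chi_mean = mean(chi), chi_rel_mean = mean(chi_rel, na.rm = TRUE),
    A_sister = A_sister, A_correct = A_correct, delta_A = dA,
    n_random = n_random,
    chi_random_mean = mean(chi_r), chi_random_se = se(chi_r),
    chi_rel_random_mean = mean(chir_r), chi_rel_random_se = se(chir_r),
    delta_A_random_mean = mean(dA_r), delta_A_random_se = se(dA_r),
    chi_ratio = mean(chi) / mean(chi_r),
    chi_rel_ratio = mean(chi_rel, na.rm = TRUE) / mean(chir_r),
    delta_A_ratio = if (mean(dA_r) > 0) dA / mean(dA_r) else NaN,
    subset = idx, method = matching$method),
    class = "match_evaluation")
}

#' @export
print.match_evaluation <- function(x, ...) {
  cat(sprintf("<match_evaluation> N = %d cells, %d species, method = %s\n",
              length(x$chi), length(x$subset), x$method))
  cat(sprintf("  mean chi     = %.5g  (random %.5g, ratio %.3g)\n",
              x$chi_mean, x$chi_random_mean, x$chi_ratio))
  cat(sprintf("  mean chi_rel = %.5g  (random %.5g, ratio %.3g)\n",
              x$chi_rel_mean, x$chi_rel_random_mean, x$chi_rel_ratio))
  cat(sprintf("  delta_A      = %.5g  (random %.5g, ratio %.3g)\n",
              x$delta_A, x$delta_A_random_mean, x$delta_A_ratio))
  invisible(x)
}

#' Histogram of the per-cell error distribution
#'
#' @param evaluation a `match_evaluation`.
#' @param breaks passed to [graphics::hist()]; the default uses
#'   Freedman-Diaconis bins.
#' @return Invisibly, the histogram object.
#' @export
chi_histogram <- function(evaluation, breaks = "FD") {
  stopifnot(inherits(evaluation, "match_evaluation"))
  h <- graphics::hist(evaluation$chi, breaks = breaks, plot = FALSE)
  h
}

#' @export
plot.match_evaluation <- function(x, ...) {
  h <- chi_histogram(x)
  graphics::plot(h, freq = FALSE, main = "P(chi)", xlab = "chi", ...)
  graphics::abline(v = x$chi_random_mean, col = "red", lty = 2)
  invisible(x)
}
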