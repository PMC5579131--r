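#' Estimate population moments of a species subset
#'
#' Computes the mean vector and the covariance matrix of the chosen species
#' over all cells of a snapshot, together with the inverse and the principal
#' symmetric inverse square root of the covariance. The covariance uses the
#' biased 1/N normalisation: downstream bin-width rules inherit this
#' convention, so it is applied exactly.
#'
#' @param snap a [snapshot].
#' @param subset species names or indices (defaults to all species).
#' @param ridge non-negative ridge added to the diagonal before inversion.
#'   Default 0; on singularity the error message suggests a value.
#' @return An object of class `covariance_model` with fields `subset`
#'   (indices), `species`, `mu`, `J`, `J_inv`, `J_inv_sqrt`, `ridge_used`.
#' @export
estimate_moments <- function(snap, subset = NULL, ridge = 0) {
  stopifnot(inherits(snap, "snapshot"))
  if (is.null(subset)) subset <- seq_along(snap$species)
  idx <- subset_indices(snap$species, subset)
  k <- length(idx)
  X <- snap$abundances[, idx, drop = FALSE]
  N <- nrow(X)
  if (N < 2L)
    stop("covariance estimation needs at least 2 cells")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  J <- crossprod(Xc) / N          # biased 1/N estimator
  Jr <- J + diag(ridge, k)
  ee <- eigen(Jr, symmetric = TRUE)
  if (min(ee$values) <= 0) {
    v <- diag(J)
    worst <- snap$species[idx][which.min(v)]
    stop(sprintf(paste0(
      "singular covariance (smallest eigenvalue %.3g); species '%s' is ",
      "near-constant. Consider ridge = %.3g."),
      min(ee$values), worst, 1e-9 * sum(diag(J)) / k))
  }
  S <- ee$vectors %*% (t(ee$vectors) / sqrt(ee$values))
  S <- (S + t(S)) / 2
  Jinv <- ee$vectors %*% (t(ee$vectors) / ee$values)
  Jinv <- (Jinv + t(Jinv)) / 2
  structure(list(subset = idx, species = snap$species[idx], mu = mu, J = J,
                 J_inv = Jinv, J_inv_sqrt = S, ridge_used = ridge,
                 time = snap$time, n_cells = N),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> t = %g, k = %d species, N = %d cells, ridge = %g\n",
              x$time, length(x$subset), x$n_cells, x$ridge_used))
  invisible(x)
}

#' Principal symmetric inverse square root of a PSD matrix
#'
#' Returns the symmetric matrix S such that `S (J + ridge I) S = I`, via
#' symmetric eigendecomposition. The principal symmetric root is required for
#' the whitening construction: the cross-time map of whitened abundances is
#' orthogonal only for a symmetric choice of root.
#'
#' @param J symmetric numeric matrix.
#' @param ridge non-negative diagonal regularisation.
#' @return Symmetric matrix of the same dimension.
#' @export
inverse_sqrt_psd <- function(J, ridge = 0) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("'J' must be square")
  nrmJ <- max(abs(J), 1e-300)
  if (max(abs(J - t(J))) > 1e-8 * nrmJ)
    stop("'J' must be symmetric")
  J <- (J + t(J)) / 2
  ee <- eigen(J + diag(ridge, nrow(J)), symmetric = TRUE)
  if (min(ee$values) < -1e-10 * nrmJ)
    stop(sprintf("matrix is not positive semidefinite (eigenvalue %.3g)",
                 min(ee$values)))
  if (min(ee$values) <= 0)
    stop("matrix is singular after ridge; increase 'ridge'")
  S <- ee$vectors %*% (t(ee$vectors) / sqrt(ee$values))
  (S + t(S)) / 2
}

new_invariant_values <- function(kind, subset, time, values) {
  structure(list(kind = kind, subset = subset, time = time,
                 values = as.numeric(values)),
            class = "invariant_values")
}

#' @export
print.invariant_values <- function(x, ...) {
  cat(sprintf("<invariant_values> %s over %d species at t = %g: N = %d, range [%.4g, %.4g]\n",
              x$kind, length(x$subset), x$time, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Total-abundance invariant I_T
#'
#' Per-cell sum of the abundances of a species subset. For a closed system of
#' first-order reactions whose rate matrix has zero column sums (or, more
#' generally, any reaction scheme that only interconverts subset members) this
#' total is exactly conserved along each cell's trajectory while differing
#' between cells, making it a per-cell tag for matching.
#'
#' @param snap a [snapshot].
#' @param subset species names or indices (defaults to all species).
#' @return An `invariant_values` object (`kind = "IT"`).
#' @export
compute_IT <- function(snap, subset = NULL) {
  stopifnot(inherits(snap, "snapshot"))
  if (is.null(subset)) subset <- seq_along(snap$species)
  idx <- subset_indices(snap$species, subset)
  vals <- rowSums(snap$abundances[, idx, drop = FALSE])
  new_invariant_values("IT", idx, snap$time, vals)
}

#' Whitened-magnitude invariant I_M
#'
#' Per-cell Euclidean norm of the abundance vector after scaling by the
#' inverse symmetric square root of the population covariance at the same
#' time point: `I_M = |J^{-1/2} x| = sqrt(x' J^{-1} x)` on the raw
#' (uncentred) abundances. Under closed linear first-order kinetics the
#' whitened vectors at two times are related by an orthogonal map, so I_M is
#' invariant per cell; for more general kinetics it typically evolves slowly.
#'
#' @param snap a [snapshot].
#' @param subset species names or indices (defaults to all species).
#' @param cov optional [estimate_moments()] result for this snapshot/subset;
#'   computed if missing.
#' @param ridge ridge passed to [estimate_moments()] when `cov` is missing.
#' @param center if `TRUE`, abundances are mean-centred before whitening.
#'   The default (`FALSE`) whitens the raw vector; the invariance argument
#'   holds for raw vectors because means transform by the same linear map.
#' @return An `invariant_values` object (`kind = "IM"`).
#' @export
compute_IM <- function(snap, subset = NULL, cov = NULL, ridge = 0,
                       center = FALSE) {
  stopifnot(inherits(snap, "snapshot"))
  if (is.null(subset)) subset <- seq_along(snap$species)
  idx <- subset_indices(snap$species, subset)
  if (is.null(cov)) cov <- estimate_moments(snap, idx, ridge = ridge)
  if (!identical(cov$subset, idx))
    stop("'cov' was estimated on a different species subset")
  X <- snap$abundances[, idx, drop = FALSE]
  if (center) X <- sweep(X, 2L, cov$mu)
  Xt <- X %*% cov$J_inv_sqrt        # whitened abundances (S symmetric)
  vals <- sqrt(rowSums(Xt * Xt))
  new_invariant_values("IM", idx, snap$time, vals)
}
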