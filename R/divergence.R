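#' Histogram two samples on a shared uniform grid
#'
#' Builds uniform bins of the given width spanning the pooled range of both
#' samples (bins are left-closed, the last bin right-closed) and returns the
#' per-bin probability masses of each sample.
#'
#' @param values1,values2 non-empty numeric vectors.
#' @param bin_width positive bin width.
#' @return A list of class `histogram_pair` with `edges`, `p1`, `p2`,
#'   `bin_width`.
#' @export
common_histograms <- function(values1, values2, bin_width) {
  if (!length(values1) || !length(values2))
    stop("both samples must be non-empty")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("'bin_width' must be positive")
  lo <- min(values1, values2)
  hi <- max(values1, values2)
  r <- (hi - lo) / bin_width
  nb <- max(1L, ceiling(r - 1e-9 * max(1, r)))
  if (nb > 1e6)
    stop(sprintf("bin count %.0f exceeds 1e6; use a larger bin width", nb))
  mass <- function(v) {
    idx <- floor((v - lo) / bin_width) + 1
    idx[idx > nb] <- nb            # right-close the last bin
    idx[idx < 1L] <- 1L
    tabulate(idx, nbins = nb) / length(v)
  }
  structure(list(edges = lo + bin_width * (0:nb),
                 p1 = mass(values1), p2 = mass(values2),
                 bin_width = bin_width),
            class = "histogram_pair")
}

kl_mass <- function(p, m) {
  pos <- p > 0
  sum(p[pos] * log(p[pos] / m[pos]))
}

#' Jensen-Shannon divergence between two binned samples
#'
#' JSD(P1, P2) = (d_KL(P1 || M) + d_KL(P2 || M)) / 2 with M = (P1 + P2)/2,
#' computed on the shared-grid bin masses of [common_histograms()] (the bin
#' widths cancel inside the logarithm, so the mass form equals the discretised
#' density integral). Zero-mass bins contribute nothing; the result lies in
#' [0, ln 2], with 0 for identical samples and ln 2 for disjoint supports.
#'
#' @inheritParams common_histograms
#' @return A number in `[0, log(2)]` (nats).
#' @export
jsd <- function(values1, values2, bin_width) {
  h <- common_histograms(values1, values2, bin_width)
  jsd_masses(h$p1, h$p2)
}

jsd_masses <- function(p1, p2) {
  m <- (p1 + p2) / 2
  d <- (kl_mass(p1, m) + kl_mass(p2, m)) / 2
  min(max(d, 0), log(2))
}

#' Bin width for the total-abundance invariant
#'
#' The histogram bin width for I_T is the cardinality k of the species
#' subset: each member abundance is resolved at copy-number granularity
#' (one molecule), so the sum of k members is resolved at k.
#'
#' @param subset species indices or names (only its length is used).
#' @return The cardinality k.
#' @export
bin_width_IT <- function(subset) {
  k <- length(subset)
  if (!k) stop("subset must be non-empty")
  k
}

#' Bin width for the whitened-magnitude invariant
#'
#' Propagates a one-molecule uncertainty in every species abundance through
#' I_M = sqrt(x' J^{-1} x): per cell, dI_M = (sum_ij J^{-1}_ij x_j) / I_M,
#' evaluated at each of the two time points with that time's own covariance.
#' The bin width is the minimum of |dI_M| over all cells at both times,
#' floored at (pooled range of I_M)/1e5 to guard degenerate samples. Cells
#' with I_M = 0 are skipped with a warning.
#'
#' @param snap1,snap2 the two [snapshot]s.
#' @param cov1,cov2 [estimate_moments()] results for the same subset at each
#'   time.
#' @param subset species indices or names.
#' @param im1,im2 optional precomputed `invariant_values` for I_M at each
#'   time (saves recomputation).
#' @return A positive bin width.
#' @export
bin_width_IM <- function(snap1, snap2, cov1, cov2, subset,
                         im1 = NULL, im2 = NULL) {
  idx <- subset_indices(snap1$species, subset)
  if (is.null(im1)) im1 <- compute_IM(snap1, idx, cov = cov1)
  if (is.null(im2)) im2 <- compute_IM(snap2, idx, cov = cov2)
  per_cell <- function(snap, cov, im) {
    X <- snap$abundances[, idx, drop = FALSE]
    num <- as.numeric(X %*% rowSums(cov$J_inv))   # sum_ij Jinv_ij x_j per cell
    ok <- im$values > 0
    if (!all(ok))
      warning(sprintf("%d cell(s) with I_M = 0 skipped in bin-width rule",
                      sum(!ok)))
    abs(num[ok]) / im$values[ok]
  }
  d <- c(per_cell(snap1, cov1, im1), per_cell(snap2, cov2, im2))
  rng <- diff(range(im1$values, im2$values))
  floorv <- if (rng > 0) rng / 1e5 else .Machine$double.eps
  if (!length(d)) return(floorv)
  max(min(d), floorv)
}

#' JSD of one species' abundance between two snapshots
#'
#' @param snap1,snap2 [snapshot]s sharing the species panel.
#' @param species a single species name or index.
#' @param bin_width histogram bin width; the default 1 reflects copy-number
#'   granularity.
#' @return A number in `[0, log(2)]`.
#' @export
species_jsd <- function(snap1, snap2, species, bin_width = 1) {
  i <- subset_indices(snap1$species, species)
  if (length(i) != 1L) stop("'species' must name a single species")
  jsd(snap1$abundances[, i], snap2$abundances[, i], bin_width)
}

#' Flag species whose distributions are stationary across a series
#'
#' A vanishing JSD for an invariant is only informative when the underlying
#' kinetics is out of steady state; in a stationary regime every variable's
#' distribution is frozen and low JSD says nothing about per-cell slowness.
#' That situation is detectable from the data: all individual species
#' distributions are unchanged across time.
#'
#' @param series a [snapshot_series] with at least two snapshots.
#' @param threshold JSD (nats) below which a species counts as unchanged.
#' @param bin_width per-species histogram width (default 1).
#' @return A list with `species_jsd` (named vector, first vs last snapshot),
#'   `flagged` (logical), and `stationary` (`TRUE` when all species are
#'   flagged, in which case slow-variable claims are unreliable).
#' @export
steady_state_check <- function(series, threshold = 0.01, bin_width = 1) {
  stopifnot(inherits(series, "snapshot_series"))
  if (length(series$snapshots) < 2L)
    stop("need at least two snapshots")
  s1 <- series$snapshots[[1L]]
  s2 <- series$snapshots[[length(series$snapshots)]]
  js <- vapply(seq_along(s1$species), function(i)
    jsd(s1$abundances[, i], s2$abundances[, i], bin_width), numeric(1))
  names(js) <- s1$species
  flagged <- js < threshold
  list(species_jsd = js, flagged = flagged, stationary = all(flagged))
}
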