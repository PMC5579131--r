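#' Analysis configuration
#'
#' Bundles the tunable knobs of the divergence/subset analysis with their
#' defaults. Defaults follow copy-number granularity (species bin width 1),
#' no covariance regularisation, and a steady-state JSD threshold of 0.01
#' nats.
#'
#' @param species_bin_width histogram bin width for individual species.
#' @param ridge covariance ridge (added to the diagonal) for I_M.
#' @param seed integer seed for seeded steps.
#' @param n_random number of random pairings R used for baselines.
#' @param steady_state_threshold per-species JSD below which a species counts
#'   as stationary.
#' @param k_max maximum subset cardinality scanned (`Inf` = up to n).
#' @param center_IM whether to mean-centre abundances before whitening.
#' @param chi_squared if `TRUE`, the per-cell matching error is reported as a
#'   squared distance instead of a distance.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(species_bin_width = 1, ridge = 0, seed = 1L,
                            n_random = 100L, steady_state_threshold = 0.01,
                            k_max = Inf, center_IM = FALSE,
                            chi_squared = FALSE) {
  cfg <- list(species_bin_width = species_bin_width, ridge = ridge,
              seed = as.integer(seed), n_random = as.integer(n_random),
              steady_state_threshold = steady_state_threshold,
              k_max = k_max, center_IM = center_IM,
              chi_squared = chi_squared)
  num <- unlist(cfg[c("species_bin_width", "ridge", "steady_state_threshold")])
  if (any(!is.finite(num))) stop("configuration values must be finite")
  structure(cfg, class = "analysis_config")
}

#' Number of species subsets excluding singletons and the empty set
#'
#' With n measured species there are `2^n - n - 1` subsets of cardinality at
#' least 2; these are the candidate manifolds on which an invariant can be a
#' slow variable.
#'
#' @param n number of measured species (>= 2).
#' @return Integer count.
#' @examples
#' count_subsets(14) # 16369
#' @export
count_subsets <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (n > 30L) return(2^n - n - 1)
  as.integer(2^n - n - 1)
}

#' Enumerate species subsets by cardinality class
#'
#' Subsets are organised into classes of equal cardinality k and enumerated
#' in lexicographic order within each class, so every subset has a stable
#' (class k, index m) address across runs.
#'
#' @param n number of species.
#' @param k_min,k_max cardinality range, `2 <= k_min <= k_max <= n`.
#' @return A list with one element per subset (integer index vectors), in
#'   class order then lexicographic order; attributes `k` and `m` give the
#'   class and within-class index of each subset.
#' @export
enumerate_subsets <- function(n, k_min = 2L, k_max = n) {
  n <- as.integer(n); k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (!(2L <= k_min && k_min <= k_max && k_max <= n))
    stop("need 2 <= k_min <= k_max <= n")
  out <- vector("list", 0L)
  ks <- integer(0); ms <- integer(0)
  for (k in k_min:k_max) {
    cmb <- utils::combn(n, k)          # columns in lexicographic order
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    ks <- c(ks, rep.int(k, ncol(cmb)))
    ms <- c(ms, seq_len(ncol(cmb)))
  }
  attr(out, "k") <- ks
  attr(out, "m") <- ms
  out
}

subset_label <- function(idx, species = NULL) {
  if (is.null(species)) paste(idx, collapse = "+")
  else paste(species[idx], collapse = "+")
}

#' Score one species subset between two snapshots
#'
#' Computes the Jensen-Shannon divergence of I_T (bin width = cardinality k)
#' and of I_M (bin width from the one-molecule propagation rule, covariance
#' estimated independently at each time point), together with the JSDs of the
#' member species, and classifies the invariants: *invariant* when the JSD is
#' exactly 0, *slow* when it is strictly below the slowest member species'
#' JSD, *fast* otherwise.
#'
#' @param snap1,snap2 [snapshot]s sharing the species panel.
#' @param subset species names or indices (cardinality >= 2).
#' @param config an [analysis_config()].
#' @param species_jsds optional precomputed per-species JSD vector over the
#'   full panel (as from [steady_state_check()]), to avoid recomputation.
#' @return A list of class `subset_score` with fields `subset`, `k`,
#'   `jsd_IT`, `jsd_IM` (NA when the covariance is singular), `species_jsds`,
#'   `slow_IT`, `slow_IM`, `status_IT`, `status_IM`.
#' @export
score_subset <- function(snap1, snap2, subset, config = analysis_config(),
                         species_jsds = NULL) {
  idx <- subset_indices(snap1$species, subset)
  if (length(idx) < 2L) stop("subset cardinality must be at least 2")
  if (!identical(snap1$species, snap2$species))
    stop("snapshots must share the species panel")
  k <- length(idx)
  if (is.null(species_jsds)) {
    sj <- vapply(idx, function(i)
      jsd(snap1$abundances[, i], snap2$abundances[, i],
          config$species_bin_width), numeric(1))
  } else {
    sj <- species_jsds[idx]
  }
  names(sj) <- snap1$species[idx]

  it1 <- compute_IT(snap1, idx); it2 <- compute_IT(snap2, idx)
  jsd_IT <- jsd(it1$values, it2$values, bin_width_IT(idx))

  jsd_IM <- NA_real_
  im_ok <- TRUE
  res <- tryCatch({
    cov1 <- estimate_moments(snap1, idx, ridge = config$ridge)
    cov2 <- estimate_moments(snap2, idx, ridge = config$ridge)
    im1 <- compute_IM(snap1, idx, cov = cov1, center = config$center_IM)
    im2 <- compute_IM(snap2, idx, cov = cov2, center = config$center_IM)
    w <- bin_width_IM(snap1, snap2, cov1, cov2, idx, im1 = im1, im2 = im2)
    jsd(im1$values, im2$values, w)
  }, error = function(e) { im_ok <<- FALSE; NA_real_ })
  if (im_ok) jsd_IM <- res

  classify <- function(j) {
    if (is.na(j)) return(NA_character_)
    if (j == 0 && min(sj) == 0) return("invariant")
    if (j < min(sj)) return(if (j == 0) "invariant" else "slow")
    "fast"
  }
  structure(list(subset = idx, species = snap1$species[idx], k = k,
                 jsd_IT = jsd_IT, jsd_IM = jsd_IM, species_jsds = sj,
                 slow_IT = jsd_IT < min(sj),
                 slow_IM = if (is.na(jsd_IM)) NA else jsd_IM < min(sj),
                 status_IT = classify(jsd_IT),
                 status_IM = classify(jsd_IM)),
            class = "subset_score")
}

#' @export
print.subset_score <- function(x, ...) {
  cat(sprintf("<subset_score> {%s} (k = %d)\n",
              paste(x$species, collapse = ", "), x$k))
  cat(sprintf("  JSD(I_T) = %.4g [%s]   JSD(I_M) = %.4g [%s]\n",
              x$jsd_IT, x$status_IT, x$jsd_IM, x$status_IM))
  cat(sprintf("  species JSD range [%.4g, %.4g]\n",
              min(x$species_jsds), max(x$species_jsds)))
  invisible(x)
}

#' Scan all species subsets of a snapshot pair
#'
#' Enumerates every subset in classes `k_min..k_max`, scores the JSD of I_T
#' and I_M for each (see [score_subset()]), and returns the results as one
#' table. The per-subset covariance for I_M is the submatrix of the full
#' panel covariance, which makes the exhaustive scan tractable; enumeration
#' is capped at 20 species.
#'
#' @param snap1,snap2 [snapshot]s sharing the species panel.
#' @param k_min,k_max cardinality range (default 2..n, capped by
#'   `config$k_max`).
#' @param invariant which invariants to score: `"both"`, `"IT"` or `"IM"`.
#' @param config an [analysis_config()].
#' @return An object of class `subset_scan`: a list with `table` (data frame
#'   with columns `k`, `m`, `subset_id`, `jsd_IT`, `jsd_IM`,
#'   `jsd_species_min`, `jsd_species_max`, `slow_IT`, `slow_IM`), `subsets`
#'   (list of index vectors), `species`, `species_jsds`, `times` and
#'   `stationary` (steady-state diagnostic over the full panel).
#' @export
scan_subsets <- function(snap1, snap2, k_min = 2L, k_max = NULL,
                         invariant = c("both", "IT", "IM"),
                         config = analysis_config()) {
  invariant <- match.arg(invariant)
  stopifnot(inherits(snap1, "snapshot"), inherits(snap2, "snapshot"))
  if (!identical(snap1$species, snap2$species))
    stop("snapshots must share the species panel")
  n <- length(snap1$species)
  if (n > 20L)
    stop("exhaustive enumeration is capped at 20 species; score an explicit ",
         "subset list with score_subset()")
  if (is.null(k_max)) k_max <- min(n, config$k_max)
  k_max <- as.integer(min(k_max, n))
  subsets <- enumerate_subsets(n, k_min, k_max)
  ks <- attr(subsets, "k"); ms <- attr(subsets, "m")

  X1 <- snap1$abundances; X2 <- snap2$abundances
  N1 <- nrow(X1); N2 <- nrow(X2)
  sj <- vapply(seq_len(n), function(i)
    jsd(X1[, i], X2[, i], config$species_bin_width), numeric(1))
  names(sj) <- snap1$species

  do_IM <- invariant %in% c("both", "IM")
  do_IT <- invariant %in% c("both", "IT")
  if (do_IM) {
    mu1 <- colMeans(X1); mu2 <- colMeans(X2)
    Jfull1 <- crossprod(sweep(X1, 2L, mu1)) / N1
    Jfull2 <- crossprod(sweep(X2, 2L, mu2)) / N2
    W1 <- if (config$center_IM) sweep(X1, 2L, mu1) else X1
    W2 <- if (config$center_IM) sweep(X2, 2L, mu2) else X2
  }

  nsub <- length(subsets)
  jsd_IT <- rep(NA_real_, nsub); jsd_IM <- rep(NA_real_, nsub)
  smin <- numeric(nsub); smax <- numeric(nsub)

  im_one_time <- function(W, Jfull, idx, ridge) {
    Js <- Jfull[idx, idx, drop = FALSE] + diag(ridge, length(idx))
    ee <- eigen(Js, symmetric = TRUE)
    if (min(ee$values) <= 0) return(NULL)
    Jinv <- ee$vectors %*% (t(ee$vectors) / ee$values)
    Xs <- W[, idx, drop = FALSE]
    M1 <- Xs %*% Jinv
    vals <- sqrt(pmax(rowSums(M1 * Xs), 0))
    list(values = vals, dI = rowSums(M1))
  }

  for (s in seq_len(nsub)) {
    idx <- subsets[[s]]
    smin[s] <- min(sj[idx]); smax[s] <- max(sj[idx])
    if (do_IT) {
      v1 <- rowSums(X1[, idx, drop = FALSE])
      v2 <- rowSums(X2[, idx, drop = FALSE])
      jsd_IT[s] <- jsd(v1, v2, length(idx))
    }
    if (do_IM) {
      a <- im_one_time(W1, Jfull1, idx, config$ridge)
      b <- im_one_time(W2, Jfull2, idx, config$ridge)
      if (!is.null(a) && !is.null(b)) {
        ok_a <- a$values > 0; ok_b <- b$values > 0
        d <- c(abs(a$dI[ok_a]) / a$values[ok_a],
               abs(b$dI[ok_b]) / b$values[ok_b])
        rng <- diff(range(a$values, b$values))
        floorv <- if (rng > 0) rng / 1e5 else .Machine$double.eps
        w <- if (length(d)) max(min(d), floorv) else floorv
        jsd_IM[s] <- jsd(a$values, b$values, w)
      }
    }
  }

  tab <- data.frame(
    k = ks, m = ms,
    subset_id = vapply(subsets, subset_label, character(1),
                       species = snap1$species),
    jsd_IT = jsd_IT, jsd_IM = jsd_IM,
    jsd_species_min = smin, jsd_species_max = smax,
    slow_IT = jsd_IT < smin, slow_IM = jsd_IM < smin,
    stringsAsFactors = FALSE)

  ss <- list(species_jsd = sj,
             flagged = sj < config$steady_state_threshold)
  ss$stationary <- all(ss$flagged)
  if (ss$stationary)
    warning("all species distributions are stationary across this interval; ",
            "low invariant JSDs do not indicate slow variables here")

  structure(list(table = tab, subsets = subsets, species = snap1$species,
                 species_jsds = sj, times = c(snap1$time, snap2$time),
                 stationary = ss$stationary, config = config,
                 invariant = invariant),
            class = "subset_scan")
}

#' @export
print.subset_scan <- function(x, ...) {
  cat(sprintf("<subset_scan> %d subsets of %d species, t = %g vs %g%s\n",
              nrow(x$table), length(x$species), x$times[1], x$times[2],
              if (x$stationary) " [STATIONARY REGIME]" else ""))
  cat(sprintf("  slow I_T: %d   slow I_M: %d\n",
              sum(x$table$slow_IT, na.rm = TRUE),
              sum(x$table$slow_IM, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.subset_scan <- function(object, which = c("IM", "IT"), ...) {
  which <- match.arg(which)
  rk <- rank_subsets(object, which)
  cat(sprintf("Per-class minima of JSD(I_%s):\n", sub("I", "", which)))
  print(rk, digits = 4)
  invisible(rk)
}

#' Per-class winners of a subset scan
#'
#' For each cardinality class, finds the subset minimising the chosen
#' invariant's JSD (ties broken by the lexicographically smallest subset,
#' which is the first enumerated) and reports, for the winner, the JSDs of
#' its fastest and slowest member species.
#'
#' @param scan a [scan_subsets()] result (or a `subset_score` list covering
#'   complete classes).
#' @param which `"IT"` or `"IM"`.
#' @return A data frame with one row per class: `k`, `n_subsets`,
#'   `best_subset`, `min_jsd`, `jsd_slowest_species`, `jsd_fastest_species`,
#'   `slow`, and the winning subset indices in the `subset` list column.
#' @export
rank_subsets <- function(scan, which = c("IM", "IT")) {
  which <- match.arg(which)
  stopifnot(inherits(scan, "subset_scan"))
  col <- paste0("jsd_", which)
  tab <- scan$table
  out <- lapply(sort(unique(tab$k)), function(k) {
    rows <- which(tab$k == k)
    if (!length(rows)) stop("empty class k = ", k)
    v <- tab[[col]][rows]
    if (all(is.na(v))) {
      best <- NA_integer_
      return(data.frame(k = k, n_subsets = length(rows),
                        best_subset = NA_character_, min_jsd = NA_real_,
                        jsd_slowest_species = NA_real_,
                        jsd_fastest_species = NA_real_, slow = NA,
                        stringsAsFactors = FALSE))
    }
    best <- rows[which.min(v)]   # first minimum = lexicographically smallest
    idx <- scan$subsets[[best]]
    data.frame(k = k, n_subsets = length(rows),
               best_subset = tab$subset_id[best], min_jsd = tab[[col]][best],
               jsd_slowest_species = min(scan$species_jsds[idx]),
               jsd_fastest_species = max(scan$species_jsds[idx]),
               slow = tab[[paste0("slow_", which)]][best],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "which") <- which
  attr(res, "subsets") <- lapply(res$best_subset, function(id) {
    if (is.na(id)) return(NA_integer_)
    match(strsplit(id, "+", fixed = TRUE)[[1L]], scan$species)
  })
  res
}

#' Plot per-class minimum JSD of a subset scan
#'
#' Mirrors the standard diagnostic: the class minimum of the invariant's JSD
#' against the JSDs of the slowest and fastest member species of the winning
#' subset.
#'
#' @param x a `subset_scan`.
#' @param which `"IM"` or `"IT"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subset_scan <- function(x, which = c("IM", "IT"), ...) {
  which <- match.arg(which)
  rk <- rank_subsets(x, which)
  ylim <- range(0, rk$min_jsd, rk$jsd_fastest_species, na.rm = TRUE)
  graphics::plot(rk$k, rk$min_jsd, type = "b", pch = 19, ylim = ylim,
                 xlab = "class cardinality k",
                 ylab = sprintf("JSD (nats)"), ...)
  graphics::points(rk$k, rk$jsd_slowest_species, type = "b", pch = 1,
                   col = "blue")
  graphics::points(rk$k, rk$jsd_fastest_species, type = "b", pch = 2,
                   col = "darkorange")
  graphics::legend("topright", bty = "n", pch = c(19, 1, 2),
                   col = c("black", "blue", "darkorange"),
                   legend = c(sprintf("min JSD(I_%s)", sub("I", "", which)),
                              "slowest member species",
                              "fastest member species"))
  invisible(rk)
}
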