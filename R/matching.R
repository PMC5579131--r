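new_matching <- function(perm, cost_E, method, kind = NULL, subset = NULL,
                         I1 = NULL, I2 = NULL, times = c(NA_real_, NA_real_),
                         cell_ids1 = NULL, cell_ids2 = NULL) {
  structure(list(perm = as.integer(perm), cost_E = cost_E, method = method,
                 kind = kind, subset = subset, I1 = I1, I2 = I2,
                 times = times, cell_ids1 = cell_ids1, cell_ids2 = cell_ids2),
            class = "cell_matching")
}

#' @export
print.cell_matching <- function(x, ...) {
  cat(sprintf("<cell_matching> %d cells, method = %s%s\n",
              length(x$perm), x$method,
              if (!is.null(x$kind)) paste0(" (", x$kind, ")") else ""))
  if (!is.null(x$cost_E)) cat(sprintf("  cost E = %.6g\n", x$cost_E))
  invisible(x)
}

#' @export
summary.cell_matching <- function(object, ...) {
  cat(sprintf("Matching of %d cells by %s\n", length(object$perm),
              object$method))
  if (!is.null(object$I1)) {
    d <- object$I1 - object$I2[object$perm]
    cat(sprintf("  invariant residuals: mean |dI| = %.4g, max |dI| = %.4g\n",
                mean(abs(d)), max(abs(d))))
    cat(sprintf("  cost E = %.6g\n", object$cost_E))
  }
  invisible(object)
}

#' Plot matched invariant values across the time interval
#'
#' Draws each cell's invariant value at the two time points joined by its
#' matching assignment; for a rank (sort) matching the connecting segments
#' never cross.
#'
#' @param x a `cell_matching` with stored invariant values.
#' @param max_cells at most this many cells are drawn (subsampled).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cell_matching <- function(x, max_cells = 200L, ...) {
  if (is.null(x$I1)) stop("this matching stores no invariant values")
  n <- length(x$I1)
  keep <- if (n > max_cells) sort(sample.int(n, max_cells)) else seq_len(n)
  t1 <- x$times[1]; t2 <- x$times[2]
  if (anyNA(x$times)) { t1 <- 0; t2 <- 1 }
  graphics::plot(NA, xlim = c(t1, t2), ylim = range(x$I1, x$I2),
                 xlab = "time", ylab = paste0("I (", x$kind %||% x$method, ")"),
                 ...)
  graphics::segments(t1, x$I1[keep], t2, x$I2[x$perm][keep],
                     col = grDevices::grey(0.4, 0.5))
  graphics::points(rep(t1, length(keep)), x$I1[keep], pch = 20, cex = 0.5)
  graphics::points(rep(t2, length(keep)), x$I2[x$perm][keep], pch = 20,
                   cex = 0.5)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match cells across time by sorting an invariant
#'
#' Pairs the cells of two snapshots so that the total squared invariant
#' discrepancy `E = sum_a (I(a, t1) - I(match(a), t2))^2` is minimised. For a
#' one-dimensional cost of this form the global optimum is attained by rank
#' pairing: both value vectors are stably sorted (ties keep original order)
#' and cells of equal rank are connected, in O(N log N). Any tie-consistent
#' pairing attains the same E.
#'
#' @param I1,I2 `invariant_values` of the same kind/subset at the two times,
#'   equal cell counts.
#' @return A `cell_matching` with `perm` mapping t1 cell index to t2 cell
#'   index and the recomputed cost `cost_E`.
#' @export
match_by_invariant <- function(I1, I2) {
  stopifnot(inherits(I1, "invariant_values"), inherits(I2, "invariant_values"))
  if (!identical(I1$kind, I2$kind) || !identical(I1$subset, I2$subset))
    stop("invariants must share kind and subset")
  n <- length(I1$values)
  if (length(I2$values) != n)
    stop("unequal cell counts; use downsample_to_match() first")
  o1 <- order(I1$values)                 # stable: ties by original index
  o2 <- order(I2$values)
  perm <- integer(n)
  perm[o1] <- o2
  cost <- sum((I1$values - I2$values[perm])^2)
  new_matching(perm, cost, "invariant_sort", kind = I1$kind,
               subset = I1$subset, I1 = I1$values, I2 = I2$values,
               times = c(I1$time, I2$time))
}

#' Match cells by minimising total Euclidean distance in species space
#'
#' The baseline matcher: pairs cells so that the total squared Euclidean
#' distance between the measured abundance vectors at the two times is small.
#' `mode = "exact"` solves the linear assignment problem (Jonker-Volgenant
#' shortest augmenting paths, O(N^3)); `mode = "greedy"` visits t1 cells in
#' seeded random order and assigns each its nearest still-unassigned t2 cell.
#'
#' @param snap1,snap2 [snapshot]s with equal cell counts.
#' @param subset species names or indices (defaults to all).
#' @param mode `"exact"` or `"greedy"`.
#' @param seed seed for the greedy visiting order.
#' @param max_exact_n exact mode is refused above this N (cubic cost) unless
#'   raised explicitly.
#' @return A `cell_matching`; `cost_E` is the total squared distance.
#' @export
match_euclidean <- function(snap1, snap2, subset = NULL,
                            mode = c("exact", "greedy"), seed = 1L,
                            max_exact_n = 5000L) {
  mode <- match.arg(mode)
  if (is.null(subset)) subset <- seq_along(snap1$species)
  idx <- subset_indices(snap1$species, subset)
  X1 <- snap1$abundances[, idx, drop = FALSE]
  X2 <- snap2$abundances[, idx, drop = FALSE]
  n <- nrow(X1)
  if (nrow(X2) != n)
    stop("unequal cell counts; use downsample_to_match() first")
  if (mode == "exact") {
    if (n > max_exact_n)
      stop(sprintf(paste0("exact assignment refused for N = %d > %d ",
                          "(cubic cost); raise 'max_exact_n' to override ",
                          "or use mode = 'greedy'"), n, max_exact_n))
    C <- sq_dist_matrix(X1, X2)
    perm <- solve_lap(C)
    cost <- sum(C[cbind(seq_len(n), perm)])
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    ord <- sample.int(n)
    perm <- integer(n)
    free <- rep(TRUE, n)
    free_idx <- seq_len(n)
    for (i in ord) {
      cand <- which(free)
      d <- colSums((t(X2[cand, , drop = FALSE]) - X1[i, ])^2)
      j <- cand[which.min(d)]
      perm[i] <- j
      free[j] <- FALSE
    }
    cost <- sum((X1 - X2[perm, , drop = FALSE])^2)
  }
  new_matching(perm, cost, paste0("euclidean_", mode), subset = idx,
               times = c(snap1$time, snap2$time),
               cell_ids1 = snap1$cell_ids, cell_ids2 = snap2$cell_ids)
}

sq_dist_matrix <- function(X1, X2) {
  g <- X1 %*% t(X2)
  n1 <- rowSums(X1^2); n2 <- rowSums(X2^2)
  pmax(outer(n1, n2, "+") - 2 * g, 0)
}

# Jonker-Volgenant shortest augmenting path solver for the square linear
# assignment problem. Returns perm with perm[i] = assigned column of row i.
solve_lap <- function(C) {
  C <- as.matrix(C)
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  # column index 1 is a sentinel; real columns are 2..n+1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j] = row occupying column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      jf <- which(!used)                 # free columns (incl. none of 1)
      cur <- C[i0, jf - 1L] - u[i0 + 1L] - v[jf]
      upd <- cur < minv[jf]
      if (any(upd)) {
        minv[jf[upd]] <- cur[upd]
        way[jf[upd]] <- j0
      }
      j1 <- jf[which.min(minv[jf])]
      delta <- minv[j1]
      uu <- which(used)
      u[p[uu] + 1L] <- u[p[uu] + 1L] + delta
      v[uu] <- v[uu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  perm[p[-1L]] <- seq_len(n)
  perm
}

#' Uniform random matching baseline
#'
#' @param n number of cells.
#' @param seed integer seed.
#' @return A `cell_matching` whose `perm` is a seeded uniform permutation.
#' @export
match_random <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  new_matching(sample.int(n), NA_real_, "random")
}

#' Match the cells of two snapshots
#'
#' The central fitting function: computes the chosen pairing between the
#' cells of two snapshots and returns it as a `cell_matching` object with
#' `print`, `summary` and `plot` methods. Invariant methods (`"IT"`, `"IM"`)
#' compute the invariant on the given species subset at each time point and
#' minimise the squared-invariant cost by rank matching; `"euclidean"` is the
#' total-distance baseline and `"random"` the null baseline.
#'
#' @param snap1,snap2 [snapshot]s sharing the species panel, equal cell
#'   counts.
#' @param method `"IT"`, `"IM"`, `"euclidean"` or `"random"`.
#' @param subset species names or indices (defaults to the full panel).
#' @param config an [analysis_config()] (ridge, centring, seed).
#' @param euclidean_mode `"exact"` or `"greedy"` for the Euclidean baseline.
#' @return A `cell_matching`.
#' @examples
#' net <- make_linear_network(4, conservative = TRUE, seed = 2)
#' sim <- generate_snapshot_series(net, n_cells = 200, times = c(0, 2),
#'                                 seed = 3)
#' m <- match_cells(sim$series$snapshots[[1]], sim$series$snapshots[[2]],
#'                  method = "IM")
#' m
#' @export
match_cells <- function(snap1, snap2,
                        method = c("IT", "IM", "euclidean", "random"),
                        subset = NULL, config = analysis_config(),
                        euclidean_mode = c("exact", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(snap1, "snapshot"), inherits(snap2, "snapshot"))
  if (!identical(snap1$species, snap2$species))
    stop("snapshots must share the species panel")
  if (method == "random")
    return(match_random(n_cells(snap1), seed = config$seed))
  if (method == "euclidean")
    return(match_euclidean(snap1, snap2, subset,
                           mode = match.arg(euclidean_mode),
                           seed = config$seed))
  if (is.null(subset)) subset <- seq_along(snap1$species)
  if (method == "IT") {
    I1 <- compute_IT(snap1, subset); I2 <- compute_IT(snap2, subset)
  } else {
    I1 <- compute_IM(snap1, subset, ridge = config$ridge,
                     center = config$center_IM)
    I2 <- compute_IM(snap2, subset, ridge = config$ridge,
                     center = config$center_IM)
  }
  m <- match_by_invariant(I1, I2)
  m$cell_ids1 <- snap1$cell_ids
  m$cell_ids2 <- snap2$cell_ids
  m
}

#' Export a matching as a data frame
#'
#' @param m a `cell_matching`.
#' @return Data frame with columns `cell_id_t1`, `cell_id_t2` and, when the
#'   matching stores invariant values, `I_t1`, `I_t2`.
#' @export
matching_table <- function(m) {
  stopifnot(inherits(m, "cell_matching"))
  n <- length(m$perm)
  ids1 <- m$cell_ids1 %||% as.character(seq_len(n))
  ids2 <- m$cell_ids2 %||% as.character(seq_len(n))
  df <- data.frame(cell_id_t1 = ids1, cell_id_t2 = ids2[m$perm],
                   stringsAsFactors = FALSE)
  if (!is.null(m$I1)) {
    df$I_t1 <- m$I1
    df$I_t2 <- m$I2[m$perm]
  }
  df
}
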