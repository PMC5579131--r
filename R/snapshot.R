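#' Construct a single time-stamped snapshot
#'
#' A snapshot is one destructive measurement of a cell population: a matrix of
#' non-negative species abundances (cells in rows, molecular species in
#' columns) recorded at a single time point. Cells carry opaque identifiers;
#' when none are supplied the row index at construction time is used.
#'
#' @param abundances numeric matrix, `N_cells x n_species`, non-negative, no
#'   missing values. Column names, if present, are used as species names.
#' @param time single finite numeric, the recording time in the units declared
#'   by the series metadata.
#' @param species character vector of unique species names; defaults to the
#'   column names of `abundances`.
#' @param cell_ids optional character vector of length `N_cells`.
#' @return An object of class `snapshot` with fields `time`, `species`,
#'   `abundances` and `cell_ids`.
#' @examples
#' s <- snapshot(matrix(1:6, 3, 2, dimnames = list(NULL, c("A", "B"))), time = 0)
#' s
#' @export
snapshot <- function(abundances, time, species = colnames(abundances),
                     cell_ids = NULL) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time))
    stop("'time' must be a single finite number")
  if (is.null(species))
    species <- paste0("x", seq_len(ncol(abundances)))
  species <- as.character(species)
  if (length(species) != ncol(abundances))
    stop("length(species) must equal ncol(abundances)")
  if (anyDuplicated(species))
    stop("species names must be unique: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  if (anyNA(abundances))
    stop("abundances contain missing values")
  if (any(abundances < 0)) {
    bad <- which(abundances < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at cell %d, species '%s'",
                 bad[1L], species[bad[2L]]))
  }
  if (is.null(cell_ids)) {
    cell_ids <- as.character(seq_len(nrow(abundances)))
  } else {
    cell_ids <- as.character(cell_ids)
    if (length(cell_ids) != nrow(abundances))
      stop("length(cell_ids) must equal nrow(abundances)")
  }
  colnames(abundances) <- species
  structure(list(time = as.numeric(time), species = species,
                 abundances = abundances, cell_ids = cell_ids),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> t = %g: %d cells x %d species (%s)\n",
              x$time, nrow(x$abundances), length(x$species),
              paste(utils::head(x$species, 6),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.snapshot <- function(x) dim(x$abundances)

n_cells <- function(s) nrow(s$abundances)

#' Construct a series of snapshots
#'
#' Bundles snapshots taken at strictly increasing times over the same species
#' panel. All downstream computations (invariants, divergence scans, matching)
#' act on pairs or chains of snapshots from one series.
#'
#' @param snapshots list of [snapshot] objects; they are sorted by time.
#' @param metadata free-form named list recording provenance (generator seed,
#'   network id, batch mode, anonymisation permutations, ...).
#' @return An object of class `snapshot_series`.
#' @export
snapshot_series <- function(snapshots, metadata = list()) {
  if (!length(snapshots)) stop("a snapshot series needs at least one snapshot")
  if (!all(vapply(snapshots, inherits, logical(1), "snapshot")))
    stop("all elements must be 'snapshot' objects")
  times <- vapply(snapshots, `[[`, numeric(1), "time")
  snapshots <- snapshots[order(times)]
  times <- sort(times)
  if (any(diff(times) <= 0)) stop("snapshot times must be strictly increasing")
  sp <- snapshots[[1L]]$species
  for (s in snapshots[-1L])
    if (!identical(s$species, sp))
      stop("all snapshots in a series must share the identical species list")
  structure(list(snapshots = snapshots, metadata = metadata),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  times <- vapply(x$snapshots, `[[`, numeric(1), "time")
  cat(sprintf("<snapshot_series> %d time points (t = %s), %d species\n",
              length(times), paste(signif(times, 4), collapse = ", "),
              length(x$snapshots[[1L]]$species)))
  invisible(x)
}

#' @export
length.snapshot_series <- function(x) length(x$snapshots)

series_times <- function(series) {
  vapply(series$snapshots, `[[`, numeric(1), "time")
}

#' Remove single-cell identities from a tracked series
#'
#' Independently permutes the cell rows of every snapshot, turning tracked
#' (trajectory) data into anonymised snapshot data. The permutations are kept
#' in the series metadata so that reconstruction quality can later be scored
#' against the hidden ground truth; analysis code never consults them.
#'
#' @param series a [snapshot_series] with cell identities.
#' @param seed integer seed controlling the permutations.
#' @return A [snapshot_series] whose per-time multisets of abundance rows are
#'   unchanged, with `metadata$anonymised_perms` recording, for each snapshot,
#'   the original row index of each new row.
#' @export
strip_identities <- function(series, seed = 1L) {
  stopifnot(inherits(series, "snapshot_series"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  perms <- vector("list", length(series$snapshots))
  snaps <- series$snapshots
  for (i in seq_along(snaps)) {
    s <- snaps[[i]]
    p <- sample.int(n_cells(s))
    perms[[i]] <- p
    snaps[[i]] <- snapshot(s$abundances[p, , drop = FALSE], s$time,
                           s$species, cell_ids = as.character(seq_along(p)))
  }
  md <- series$metadata
  md$anonymised_perms <- perms
  md$anonymised_seed <- as.integer(seed)
  snapshot_series(snaps, md)
}

#' Downsample every snapshot of a series to a common cell count
#'
#' Matching requires equal cell counts at the two time points; this draws a
#' seeded uniform subsample without replacement from each snapshot.
#'
#' @param series a [snapshot_series].
#' @param n_target positive integer, cells to keep per snapshot.
#' @param seed integer seed.
#' @return A [snapshot_series] with `n_target` cells per snapshot.
#' @export
downsample_to_match <- function(series, n_target, seed = 1L) {
  stopifnot(inherits(series, "snapshot_series"))
  n_target <- as.integer(n_target)
  if (is.na(n_target) || n_target < 1L)
    stop("'n_target' must be a positive integer")
  sizes <- vapply(series$snapshots, n_cells, integer(1))
  if (any(sizes < n_target))
    stop(sprintf("n_target = %d exceeds the smallest snapshot (%d cells)",
                 n_target, min(sizes)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  snaps <- lapply(series$snapshots, function(s) {
    keep <- sort(sample.int(n_cells(s), n_target))
    snapshot(s$abundances[keep, , drop = FALSE], s$time, s$species,
             s$cell_ids[keep])
  })
  md <- series$metadata
  md$downsample <- list(n_target = n_target, seed = as.integer(seed))
  snapshot_series(snaps, md)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

subset_indices <- function(species_all, subset) {
  if (is.character(subset)) {
    idx <- match(subset, species_all)
    if (anyNA(idx))
      stop("unknown species: ", paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > length(species_all)))
      stop("species indices out of range")
  }
  if (!length(idx)) stop("subset must be non-empty")
  if (anyDuplicated(idx)) stop("subset contains duplicate species")
  idx
}
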