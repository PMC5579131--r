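#' Read a snapshot series from CSV
#'
#' Two dialects are supported. The canonical long format is a single CSV with
#' header `cell_id,time,<species1>,...,<speciesN>`; rows are grouped by time
#' into snapshots, with species order taken from the header. The per-time
#' format is a directory (or explicit vector) of CSVs, one per time point,
#' each with header `cell_id,<species...>` and the time encoded in the file
#' name as `t<value>.csv` (e.g. `t0.csv`, `t7.5.csv`).
#'
#' @param path file path (long format) or directory/vector of files
#'   (per-time format).
#' @param format `"long_csv"` or `"per_time_csv"`.
#' @return A [snapshot_series].
#' @seealso [write_snapshot_series()]
#' @export
read_snapshot_series <- function(path, format = c("long_csv", "per_time_csv")) {
  format <- match.arg(format)
  if (format == "long_csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("cell_id", "time")
    if (!all(need %in% names(df)))
      stop("long CSV must have columns 'cell_id' and 'time': ", path)
    species <- setdiff(names(df), need)
    if (!length(species)) stop("long CSV has no species columns: ", path)
    if (anyNA(df[species]))
      stop("missing abundance values in ", path)
    times <- sort(unique(df$time))
    snaps <- lapply(times, function(tt) {
      rows <- df[df$time == tt, , drop = FALSE]
      snapshot(as.matrix(rows[species]), tt, species,
               cell_ids = as.character(rows$cell_id))
    })
    return(snapshot_series(snaps, metadata = list(source = path)))
  }
  # per-time format
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "^t.*\\.csv$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) stop("no per-time CSV files found at: ", paste(path, collapse = ", "))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  parse_time <- function(f) {
    m <- sub("^t", "", sub("\\.csv$", "", basename(f)))
    tt <- suppressWarnings(as.numeric(m))
    if (is.na(tt)) stop("cannot parse a time from file name: ", basename(f))
    tt
  }
  species_ref <- NULL
  snaps <- lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(df))
      stop("per-time CSV must have a 'cell_id' column: ", f)
    species <- setdiff(names(df), "cell_id")
    if (is.null(species_ref)) {
      species_ref <<- species
    } else if (!identical(species, species_ref)) {
      delta <- c(setdiff(species_ref, species), setdiff(species, species_ref))
      stop("inconsistent species sets across time points (", f, "): ",
           paste(delta, collapse = ", "))
    }
    snapshot(as.matrix(df[species]), parse_time(f), species,
             cell_ids = as.character(df$cell_id))
  })
  snapshot_series(snaps, metadata = list(source = files))
}

#' Write a snapshot series to CSV
#'
#' Inverse of [read_snapshot_series()]: abundances round-trip bit-for-bit
#' (written with full precision). Long format writes a single file; per-time
#' format writes `t<value>.csv` files into the directory `path`.
#'
#' @param series a [snapshot_series].
#' @param path output file (long) or directory (per-time; created if needed).
#' @param format `"long_csv"` or `"per_time_csv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_snapshot_series <- function(series, path,
                                  format = c("long_csv", "per_time_csv")) {
  stopifnot(inherits(series, "snapshot_series"))
  format <- match.arg(format)
  if (!length(series$snapshots)) stop("cannot write an empty series")
  fmt_num <- function(x) formatC(x, format = "g", digits = 17)
  if (format == "long_csv") {
    blocks <- lapply(series$snapshots, function(s) {
      data.frame(cell_id = s$cell_ids, time = fmt_num(s$time),
                 apply(s$abundances, 2, fmt_num),
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, blocks)
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) stop("failed writing ", path, ": ",
                                conditionMessage(e)))
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  written <- vapply(series$snapshots, function(s) {
    f <- file.path(path, sprintf("t%s.csv", format(s$time, trim = TRUE)))
    df <- data.frame(cell_id = s$cell_ids, apply(s$abundances, 2, fmt_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
    tryCatch(utils::write.csv(df, f, row.names = FALSE, quote = FALSE),
             error = function(e) stop("failed writing ", f, ": ",
                                      conditionMessage(e)))
    f
  }, character(1))
  invisible(written)
}

#' Export invariant values as a long table
#'
#' @param values an `invariant_values` object from [compute_IT()] or
#'   [compute_IM()].
#' @param cell_ids optional cell identifiers (defaults to row index).
#' @param subset_id optional label for the species subset.
#' @return A data frame with columns `cell_id,time,kind,subset_id,value`.
#' @export
invariant_table <- function(values, cell_ids = NULL, subset_id = NULL) {
  stopifnot(inherits(values, "invariant_values"))
  n <- length(values$values)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
  if (is.null(subset_id)) subset_id <- paste(values$subset, collapse = "+")
  data.frame(cell_id = cell_ids, time = values$time, kind = values$kind,
             subset_id = subset_id, value = values$values,
             stringsAsFactors = FALSE)
}
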