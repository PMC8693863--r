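#' Multinucleation census containers
#'
#' A *census snapshot* records, for one time interval, how many cells carry
#' each number of nuclei. Annotation of time-lapse movies typically cannot
#' resolve nuclei counts above a small cap, so every cell with `>= cap`
#' nuclei is binned into the topmost class (`cap = 4` by default: a cell
#' with 7 nuclei is recorded as a 4-nuclei cell). A *census series* is an
#' ordered sequence of snapshots at consecutive integer intervals
#' (60-minute spacing by default).
#'
#' @param counts integer vector of length `cap`; `counts[i]` is the number
#'   of cells annotated with `i` nuclei (the top entry holds all cells with
#'   `>= cap` nuclei).
#' @param t_index integer interval index (0 at experiment onset).
#' @param cap integer `>= 2`; topmost annotated nuclei class.
#' @return `census_snapshot()` returns a named integer vector of class
#'   `"census_snapshot"` with attributes `t_index` and `cap`.
#' @examples
#' census_snapshot(c(120, 6, 2, 1))
#' @export
census_snapshot <- function(counts, t_index = 0L, cap = length(counts)) {
  if (!is_count(cap) || cap < 2) stopf("`cap` must be an integer >= 2")
  if (length(counts) != cap)
    stopf("`counts` must have length `cap` (%d), got %d", cap, length(counts))
  if (anyNA(counts) || any(counts < 0) || any(counts != as.integer(counts)))
    stopf("census counts must be non-negative integers")
  if (!is_count(t_index) || t_index < 0)
    stopf("`t_index` must be a non-negative integer")
  x <- as.integer(counts)
  names(x) <- paste0("c", seq_len(cap))
  structure(x, t_index = as.integer(t_index), cap = as.integer(cap),
            class = "census_snapshot")
}

#' @export
print.census_snapshot <- function(x, ...) {
  cat(sprintf("<census_snapshot t=%d cap=%d> ", attr(x, "t_index"),
              attr(x, "cap")))
  cat(paste(names(x), unclass(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname census_snapshot
#' @param snapshots list of `census_snapshot` objects with consecutive
#'   `t_index` and a shared `cap`, or a data frame / matrix with columns
#'   `t, c1, ..., c{cap}`.
#' @param interval_minutes physical spacing between consecutive intervals;
#'   kept as metadata only (all computations are in interval units).
#' @return `census_series()` returns a data frame of class `"census_series"`
#'   with columns `t, c1, ..., c{cap}` and attributes `cap` and
#'   `interval_minutes`.
#' @examples
#' census_series(list(
#'   census_snapshot(c(100, 0, 0, 0), t_index = 0),
#'   census_snapshot(c(96, 2, 0, 0), t_index = 1)
#' ))
#' @export
census_series <- function(snapshots, interval_minutes = 60) {
  if (!is.numeric(interval_minutes) || length(interval_minutes) != 1 ||
      interval_minutes <= 0)
    stopf("`interval_minutes` must be a positive number")
  if (is.data.frame(snapshots) || is.matrix(snapshots)) {
    df <- as.data.frame(snapshots)
    return(validate_census_df(df, interval_minutes))
  }
  if (!is.list(snapshots) || !all(vapply(snapshots, inherits, TRUE,
                                         "census_snapshot")))
    stopf("`snapshots` must be a list of census_snapshot objects")
  caps <- vapply(snapshots, attr, 0L, "cap")
  if (length(unique(caps)) != 1)
    stopf("all snapshots must share the same cap (got %s)",
          paste(unique(caps), collapse = ", "))
  ts <- vapply(snapshots, attr, 0L, "t_index")
  df <- data.frame(t = ts)
  df <- cbind(df, do.call(rbind, lapply(snapshots, unclass)))
  validate_census_df(df, interval_minutes)
}

validate_census_df <- function(df, interval_minutes = 60) {
  if (!"t" %in% names(df)) stopf("census table must have a `t` column")
  count_cols <- grep("^c[0-9]+$", names(df), value = TRUE)
  if (length(count_cols) == 0)
    stopf("census table must have count columns c1, c2, ...")
  cap <- length(count_cols)
  if (!setequal(count_cols, paste0("c", seq_len(cap))))
    stopf("count columns must be consecutive c1..c%d; found: %s", cap,
          paste(count_cols, collapse = ", "))
  if (cap < 2) stopf("census needs at least classes c1 and c2 (cap >= 2)")
  df <- df[, c("t", paste0("c", seq_len(cap)))]
  if (nrow(df) < 1) stopf("census table has no rows")
  for (col in names(df)) {
    v <- df[[col]]
    if (anyNA(v) || !is.numeric(v) || any(v != as.integer(v)))
      stopf("column `%s` must contain integers only", col)
    df[[col]] <- as.integer(v)
  }
  bad <- which(as.matrix(df[count_cols]) < 0, arr.ind = TRUE)
  if (length(bad))
    stopf("negative count at row %d (t=%d)", bad[1, 1], df$t[bad[1, 1]])
  if (nrow(df) > 1) {
    gaps <- which(diff(df$t) != 1L)
    if (length(gaps))
      stopf("interval indices must be consecutive: gap after t=%d (row %d)",
            df$t[gaps[1]], gaps[1])
  }
  structure(df, cap = as.integer(cap),
            interval_minutes = as.numeric(interval_minutes),
            class = c("census_series", "data.frame"))
}

#' @export
print.census_series <- function(x, ...) {
  cat(sprintf("<census_series: %d intervals, cap=%d, %g min spacing>\n",
              nrow(x), attr(x, "cap"), attr(x, "interval_minutes")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Extract row i of a series as a census_snapshot.
series_snapshot <- function(series, i) {
  cap <- attr(series, "cap")
  census_snapshot(as.integer(series[i, paste0("c", seq_len(cap))]),
                  t_index = series$t[i], cap = cap)
}

#' Bin a multiset of cell sizes into capped census counts
#'
#' Applies the annotation cap: cells are counted by their exact nuclei
#' number below the cap, and every cell with `>= cap` nuclei falls into the
#' topmost class.
#'
#' @param sizes integer vector of nuclei counts per cell (one entry per
#'   cell, uncapped, all `>= 1`).
#' @param cap integer `>= 2` (default 4).
#' @param t_index interval index recorded on the snapshot.
#' @return a [census_snapshot()].
#' @examples
#' bin_sizes(c(1, 2, 5, 7))  # -> c1=1 c2=1 c3=0 c4=2
#' @export
bin_sizes <- function(sizes, cap = 4L, t_index = 0L) {
  if (length(sizes) == 0)
    stopf("empty cell population: cannot bin an empty size multiset")
  if (anyNA(sizes) || any(sizes < 1) || any(sizes != as.integer(sizes)))
    stopf("cell sizes must be positive integers")
  if (!is_count(cap) || cap < 2) stopf("`cap` must be an integer >= 2")
  counts <- tabulate(pmin(as.integer(sizes), as.integer(cap)), nbins = cap)
  census_snapshot(counts, t_index = t_index, cap = cap)
}

#' Total (annotated) nuclei in a census snapshot or series
#'
#' Sums `i * counts[i]` over the size classes. For capped data this is a
#' lower bound on the true number of nuclei, since cells above the cap
#' contribute only `cap` nuclei each.
#'
#' @param x a `census_snapshot` or `census_series`.
#' @return integer (snapshot) or integer vector, one value per interval
#'   (series).
#' @examples
#' total_nuclei(census_snapshot(c(2, 1, 0, 3)))  # 2 + 2 + 12 = 16
#' @export
total_nuclei <- function(x) UseMethod("total_nuclei")

#' @export
total_nuclei.census_snapshot <- function(x) {
  sum(seq_along(x) * as.integer(x))
}

#' @export
total_nuclei.census_series <- function(x) {
  cap <- attr(x, "cap")
  m <- as.matrix(x[, paste0("c", seq_len(cap))])
  as.integer(m %*% seq_len(cap))
}

#' Fraction of nuclei in large multinucleated cells (the f4 statistic)
#'
#' The probability that a randomly chosen nucleus resides in a cell with at
#' least `threshold` nuclei. This is the statistic compared between the
#' observed census and shadow simulations; with the default threshold of 4
#' it is the "f4" fraction.
#'
#' On a capped [census_snapshot()] the numerator counts `i * counts[i]` for
#' classes `i >= threshold`, so for `threshold = cap` each large cell
#' contributes `cap` nuclei -- a lower bound on the true fraction. On a raw
#' size multiset true sizes are used unless `cap_statistic = TRUE`, which
#' reproduces the annotation distortion (every cell contributes
#' `min(size, cap)` to numerator and denominator).
#'
#' @param x a `census_snapshot`, `census_series`, or integer vector of
#'   per-cell nuclei counts.
#' @param threshold minimum nuclei count defining a "large" cell
#'   (default 4).
#' @param cap annotation cap used when `cap_statistic = TRUE` (multisets
#'   only; snapshots carry their own cap).
#' @param cap_statistic apply the annotation cap to a size multiset before
#'   computing the statistic.
#' @param multinucleated_only use only nuclei in multinucleated cells
#'   (`size >= 2`) as the denominator instead of all nuclei. Off by
#'   default: the statistic is a per-nucleus probability over the whole
#'   field.
#' @return numeric fraction in `[0, 1]` (one value per interval for a
#'   series).
#' @examples
#' statistic_f4(c(1, 1, 1, 1))        # 0: no cell reaches 4 nuclei
#' statistic_f4(c(4))                 # 1
#' statistic_f4(census_snapshot(c(6, 1, 0, 1)))  # 4/12
#' @export
statistic_f4 <- function(x, threshold = 4L, cap = 4L, cap_statistic = FALSE,
                         multinucleated_only = FALSE) {
  UseMethod("statistic_f4")
}

#' @export
statistic_f4.default <- function(x, threshold = 4L, cap = 4L,
                                 cap_statistic = FALSE,
                                 multinucleated_only = FALSE) {
  sizes <- as.integer(x)
  if (length(sizes) == 0 || anyNA(sizes) || any(sizes < 1))
    stopf("`x` must be a non-empty vector of positive cell sizes")
  if (!is_count(threshold) || threshold < 1)
    stopf("`threshold` must be a positive integer")
  eff <- if (cap_statistic) pmin(sizes, as.integer(cap)) else sizes
  den_sizes <- if (multinucleated_only) eff[sizes >= 2] else eff
  den <- sum(den_sizes)
  if (den == 0) stopf("zero total nuclei in the statistic denominator")
  sum(eff[sizes >= threshold]) / den
}

#' @export
statistic_f4.census_snapshot <- function(x, threshold = 4L, cap = 4L,
                                         cap_statistic = FALSE,
                                         multinucleated_only = FALSE) {
  snap_cap <- attr(x, "cap")
  if (!is_count(threshold) || threshold < 1 || threshold > snap_cap)
    stopf("`threshold` must be an integer in 1..cap (%d)", snap_cap)
  counts <- as.integer(x)
  i <- seq_len(snap_cap)
  den <- if (multinucleated_only) sum(i[i >= 2] * counts[i >= 2])
         else sum(i * counts)
  if (den == 0) stopf("zero total nuclei at t=%d", attr(x, "t_index"))
  sum(i[i >= threshold] * counts[i >= threshold]) / den
}

#' @export
statistic_f4.census_series <- function(x, threshold = 4L, cap = 4L,
                                       cap_statistic = FALSE,
                                       multinucleated_only = FALSE) {
  vapply(seq_len(nrow(x)), function(i) {
    statistic_f4(series_snapshot(x, i), threshold = threshold,
                 multinucleated_only = multinucleated_only)
  }, numeric(1))
}

#' Read and write census tables
#'
#' Census tables are plain delimited text (comma by default, tab accepted
#' on read) with header `t,c1,c2,...,c{cap}` and one row of exact integer
#' counts per interval. The round trip `read_census_table(write_census_table(x))`
#' is the identity on valid series.
#'
#' @param path file path.
#' @param interval_minutes spacing metadata attached to the series on read.
#' @return `read_census_table()` returns a [census_series()].
#' @export
read_census_table <- function(path, interval_minutes = 60) {
  if (!file.exists(path)) stopf("census file not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep,
                   colClasses = "numeric", check.names = TRUE)
  validate_census_df(df, interval_minutes)
}

#' @rdname read_census_table
#' @param series a `census_series`.
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_census_table <- function(series, path, sep = ",") {
  if (!inherits(series, "census_series"))
    series <- census_series(series)
  write.table(as.data.frame(series), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
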