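#' Fusion index of an annotated field
#'
#' Percentage of all nuclei in the field that reside in MyHC-positive
#' cells with at least `min_nuclei` nuclei (2 by default). The denominator
#' is the total nuclei across all cells, marker-negative cells included.
#'
#' @param cells data frame with columns `nuclei_count` (positive integer)
#'   and `myhc` (logical or 0/1 marker-positivity flag); one row per cell
#'   in one frame. A `frame` column, if present, is ignored here -- filter
#'   upstream to compute per-frame indices.
#' @param min_nuclei minimum nuclei count for a cell to count as fused.
#' @return percentage in `[0, 100]`.
#' @examples
#' cells <- data.frame(nuclei_count = c(4, 1, 1, 1, 1, 1, 1), myhc = c(1, 0, 0, 0, 0, 0, 0))
#' fusion_index(cells)  # 4 of 10 nuclei -> 40
#' @export
fusion_index <- function(cells, min_nuclei = 2L) {
  cells <- validate_cell_table(cells)
  if (nrow(cells) == 0) stopf("empty frame: no cells to index")
  total <- sum(cells$nuclei_count)
  fused <- cells$myhc & cells$nuclei_count >= min_nuclei
  100 * sum(cells$nuclei_count[fused]) / total
}

#' Nuclei distribution stratified by cell size
#'
#' Fraction of total nuclei residing in cells of each size bin. Two
#' presets match common reporting conventions for time-lapse and endpoint
#' assays:
#' * `"hourly"`: mononucleated, binucleated, trinucleated, `>= 4` nuclei;
#' * `"endpoint"`: mononucleated, binucleated, 3--10 nuclei, `> 10`
#'   nuclei.
#'
#' Custom bins are given as a two-column matrix / data frame of inclusive
#' `lo`, `hi` bounds (use `Inf` for an open top bin); bins must partition
#' the positive integers.
#'
#' @param cells data frame with a `nuclei_count` column (one row per
#'   cell). Subset to marker-positive cells upstream if a gated
#'   distribution is wanted.
#' @param bins `"hourly"`, `"endpoint"`, or a custom bin table.
#' @return named numeric vector of nuclei fractions, one per bin, summing
#'   to 1.
#' @examples
#' stratified_fusion_index(data.frame(nuclei_count = c(1, 1, 2)), "hourly")
#' @export
stratified_fusion_index <- function(cells, bins = "hourly") {
  cells <- validate_cell_table(cells, need_myhc = FALSE)
  if (nrow(cells) == 0) stopf("empty frame: no cells to stratify")
  b <- resolve_bins(bins)
  total <- sum(cells$nuclei_count)
  out <- vapply(seq_len(nrow(b)), function(i) {
    sel <- cells$nuclei_count >= b$lo[i] & cells$nuclei_count <= b$hi[i]
    sum(cells$nuclei_count[sel]) / total
  }, numeric(1))
  names(out) <- b$label
  out
}

resolve_bins <- function(bins) {
  if (is.character(bins) && length(bins) == 1) {
    b <- switch(bins,
      hourly = data.frame(lo = c(1, 2, 3, 4), hi = c(1, 2, 3, Inf),
                          label = c("mono", "bi", "tri", "4plus")),
      endpoint = data.frame(lo = c(1, 2, 3, 11), hi = c(1, 2, 10, Inf),
                            label = c("mono", "bi", "3to10", "gt10")),
      stopf("unknown bin preset \"%s\" (use \"hourly\" or \"endpoint\")", bins))
    return(b)
  }
  b <- as.data.frame(bins)
  if (!all(c("lo", "hi") %in% names(b)))
    stopf("custom bins need `lo` and `hi` columns")
  if (!"label" %in% names(b))
    b$label <- paste0(b$lo, "to", b$hi)
  b <- b[order(b$lo), ]
  if (b$lo[1] != 1 || !is.infinite(b$hi[nrow(b)]))
    stopf("bins must cover all positive integers (start at 1, end at Inf)")
  if (nrow(b) > 1 && any(b$lo[-1] != head(b$hi, -1) + 1))
    stopf("bins must be contiguous and non-overlapping")
  b
}

validate_cell_table <- function(cells, need_myhc = TRUE) {
  cells <- as.data.frame(cells)
  if (!"nuclei_count" %in% names(cells))
    stopf("cell table needs a `nuclei_count` column")
  v <- cells$nuclei_count
  if (anyNA(v) || any(v < 1) || any(v != as.integer(v)))
    stopf("`nuclei_count` must be positive integers")
  cells$nuclei_count <- as.integer(v)
  if (need_myhc) {
    if (!"myhc" %in% names(cells))
      stopf("cell table needs a `myhc` positivity column")
    cells$myhc <- as.logical(cells$myhc)
    if (anyNA(cells$myhc)) stopf("`myhc` must be logical or 0/1")
  }
  cells
}

#' Marker-positive nuclear fraction
#'
#' Percentage of nuclei positive for a named marker (e.g. MYOG, Ki-67,
#' pH3), pooled across the table or per frame. Per-frame and pooled
#' values differ when frames have unequal nuclei totals: pooling weights
#' by nuclei count.
#'
#' @param nuclei data frame with one row per nucleus, a `frame` column,
#'   and one 0/1 (or logical) column per marker.
#' @param marker name of the marker column.
#' @param per_frame return one percentage per frame instead of the pooled
#'   value.
#' @return percentage in `[0, 100]`, or a named vector of them.
#' @examples
#' nuc <- data.frame(frame = rep(1:2, c(20, 80)),
#'                   myog = c(rep(1, 10), rep(0, 10), rep(1, 30), rep(0, 50)))
#' marker_positive_fraction(nuc, "myog")              # 40
#' marker_positive_fraction(nuc, "myog", per_frame = TRUE)  # 50, 37.5
#' @export
marker_positive_fraction <- function(nuclei, marker, per_frame = FALSE) {
  nuclei <- as.data.frame(nuclei)
  if (nrow(nuclei) == 0) stopf("no nuclei in table")
  if (!marker %in% names(nuclei))
    stopf("unknown marker \"%s\"; table has: %s", marker,
          paste(setdiff(names(nuclei), c("frame", "nucleus_id")),
                collapse = ", "))
  flag <- as.logical(nuclei[[marker]])
  if (anyNA(flag)) stopf("marker column `%s` must be logical or 0/1", marker)
  if (isTRUE(per_frame)) {
    if (!"frame" %in% names(nuclei)) stopf("`frame` column required")
    p <- tapply(flag, nuclei$frame, function(f) 100 * mean(f))
    stats::setNames(as.numeric(p), names(p))
  } else {
    100 * mean(flag)
  }
}

#' Migration rate from nuclei tracks
#'
#' Computes per-track and cohort mean migration speed from nuclei
#' positions over time. For every pair of consecutive frames within a
#' track, displacement is `sqrt(dx^2 + dy^2)`; a track's speed is its mean
#' per-frame displacement divided by the frame interval. Gaps (missing
#' frames) split a track into segments -- a displacement is never computed
#' across a gap. The cohort value averages per-track speeds, so long
#' tracks do not dominate.
#'
#' @param tracks data frame with columns `nucleus_id`, `t` (integer frame
#'   index), `x_um`, `y_um` (positions in micrometres).
#' @param frame_interval_minutes time between consecutive frames.
#' @return list with `per_track` (data frame `nucleus_id, n_steps,
#'   speed_um_min`) and `cohort_mean` (mean of per-track speeds,
#'   micrometres per minute). Tracks contributing no consecutive-frame
#'   pair are excluded with a warning.
#' @examples
#' tr <- data.frame(nucleus_id = 1, t = 0:1, x_um = c(0, 3), y_um = c(0, 4))
#' migration_rate(tr, frame_interval_minutes = 5)$cohort_mean  # 1 um/min
#' @export
migration_rate <- function(tracks, frame_interval_minutes) {
  tracks <- as.data.frame(tracks)
  need <- c("nucleus_id", "t", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stopf("track table needs columns %s", paste(need, collapse = ", "))
  if (!is.numeric(frame_interval_minutes) || frame_interval_minutes <= 0)
    stopf("`frame_interval_minutes` must be positive")
  per <- lapply(split(tracks, tracks$nucleus_id), function(tr) {
    tr <- tr[order(tr$t), ]
    if (anyDuplicated(tr$t))
      stopf("track %s has duplicated frame indices", tr$nucleus_id[1])
    dt <- diff(tr$t)
    consec <- dt == 1           # gap rule: only consecutive frames count
    if (!any(consec)) return(NULL)
    d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[consec]
    data.frame(nucleus_id = tr$nucleus_id[1], n_steps = sum(consec),
               speed_um_min = mean(d) / frame_interval_minutes)
  })
  skipped <- sum(vapply(per, is.null, logical(1)))
  if (skipped > 0)
    warnf("excluded %d track(s) with fewer than 2 consecutive samples",
          skipped)
  per <- do.call(rbind, per)
  if (is.null(per)) stopf("no usable tracks (all shorter than 2 samples)")
  rownames(per) <- NULL
  list(per_track = per, cohort_mean = mean(per$speed_um_min))
}

#' Read annotation tables for the quantification metrics
#'
#' Plain delimited text with headers: cell tables
#' (`frame,cell_id,nuclei_count,myhc`), nucleus tables
#' (`frame,nucleus_id,<marker>...` with 0/1 flags), and track tables
#' (`nucleus_id,t,x_um,y_um`).
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_cell_table <- function(path) {
  df <- read_delim_table(path)
  validate_cell_table(df)
}

#' @rdname read_cell_table
#' @export
read_nucleus_table <- function(path) {
  df <- read_delim_table(path)
  if (!"nucleus_id" %in% names(df))
    stopf("nucleus table needs a `nucleus_id` column")
  if (anyDuplicated(df[c("frame", "nucleus_id")]))
    stopf("(frame, nucleus_id) pairs must be unique")
  df
}

#' @rdname read_cell_table
#' @export
read_track_table <- function(path) {
  df <- read_delim_table(path)
  need <- c("nucleus_id", "t", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stopf("track table needs columns %s", paste(need, collapse = ", "))
  df
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep)
}
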