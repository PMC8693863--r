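#' Estimate fusion events per interval from a census series
#'
#' Each pairwise fusion merges two cells; on capped counts the net effect
#' of the interval's fusions is recovered by the weighted difference of
#' multinucleated-class counts between consecutive snapshots:
#' \deqn{raw(t) = \sum_{i=2}^{cap} (C_t(i) - C_{t-1}(i)) (i - 1)}
#' where \eqn{C_t(i)} is the number of cells annotated with `i` nuclei at
#' interval `t`. The estimate assumes a closed population (no division,
#' death, or field exit). Because cells above the cap are binned, the
#' estimate is a lower bound on the true number of fusion events whenever
#' any cell's true size exceeds the cap; it is exact otherwise.
#'
#' Negative raw values (possible when multinucleated cells leave the field
#' or annotation is noisy) cannot be replayed by a simulator, so they are
#' clamped to 0 with a warning; the raw values are retained for
#' diagnostics.
#'
#' @param series a [census_series()] with at least 2 snapshots.
#' @return a data frame of class `"fusion_schedule"` with columns `t`
#'   (interval index, starting at the second snapshot), `raw` (signed
#'   estimate) and `n_fusion` (`max(raw, 0)`), and attributes
#'   `total_fusions` and `cap`.
#' @examples
#' s <- census_series(data.frame(t = 0:2, c1 = c(10, 8, 8), c2 = c(0, 1, 0),
#'                               c3 = c(0, 0, 1), c4 = 0))
#' estimate_fusion_schedule(s)
#' @export
estimate_fusion_schedule <- function(series) {
  if (!inherits(series, "census_series")) series <- census_series(series)
  if (nrow(series) < 2)
    stopf("need >= 2 snapshots to estimate a fusion schedule (got %d)",
          nrow(series))
  cap <- attr(series, "cap")
  m <- as.matrix(series[, paste0("c", seq_len(cap))])
  w <- c(0, seq_len(cap - 1))        # weight (i - 1), zero for i = 1
  raw <- as.integer(diff(m) %*% w)
  if (any(raw < 0))
    warnf("%d interval(s) had a negative raw fusion estimate (clamped to 0): t = %s",
          sum(raw < 0),
          paste(series$t[-1][raw < 0], collapse = ", "))
  sched <- data.frame(t = series$t[-1], raw = raw,
                      n_fusion = pmax(raw, 0L))
  structure(sched, total_fusions = sum(sched$n_fusion), cap = cap,
            class = c("fusion_schedule", "data.frame"))
}

#' @export
print.fusion_schedule <- function(x, ...) {
  cat(sprintf("<fusion_schedule: %d intervals, %d fusion events total>\n",
              nrow(x), attr(x, "total_fusions")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

new_fusion_schedule <- function(t, raw, n_fusion, cap = 4L) {
  sched <- data.frame(t = as.integer(t), raw = as.integer(raw),
                      n_fusion = as.integer(n_fusion))
  if (any(sched$n_fusion < 0)) stopf("n_fusion must be non-negative")
  structure(sched, total_fusions = sum(sched$n_fusion), cap = as.integer(cap),
            class = c("fusion_schedule", "data.frame"))
}

# Accept a fusion_schedule or a bare non-negative integer vector.
as_schedule_counts <- function(schedule) {
  if (inherits(schedule, "fusion_schedule")) return(schedule$n_fusion)
  if (is.numeric(schedule) && !anyNA(schedule) &&
      all(schedule >= 0 & schedule == as.integer(schedule)))
    return(as.integer(schedule))
  stopf("`schedule` must be a fusion_schedule or a non-negative integer vector")
}

#' Read and write fusion schedules
#'
#' Schedules are delimited text with header `t,raw,n_fusion`.
#'
#' @param schedule a `fusion_schedule`.
#' @param path file path.
#' @export
write_fusion_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_fusion_schedule
#' @export
read_fusion_schedule <- function(path) {
  if (!file.exists(path)) stopf("schedule file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = ",")
  need <- c("t", "raw", "n_fusion")
  if (!all(need %in% names(df)))
    stopf("schedule file must have columns %s", paste(need, collapse = ","))
  new_fusion_schedule(df$t, df$raw, df$n_fusion)
}
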