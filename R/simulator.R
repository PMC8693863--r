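#' Pairing kernels for shadow simulations
#'
#' Two null models for which cells fuse at each event:
#' * `"equal"` -- every unordered pair of distinct cells is equally likely
#'   (pure random fusion, blind to cell size);
#' * `"weighted"` -- cells are drawn sequentially without replacement with
#'   probability proportional to their nuclei count, modelling the larger
#'   contact area (and hence bump-and-fuse chance) of bigger cells under
#'   the simplistic assumption that an n-nucleated cell has n times the
#'   area of a mononucleated one.
#'
#' An alternative pair-level size-weighted law (probability of a pair
#' proportional to the product of the two sizes) is conceivable but is not
#' implemented as a kernel; sequential size-biased selection is the direct
#' reading of per-cell, size-proportional selection.
#'
#' @param kernel `"equal"` or `"weighted"`.
#' @return the matched kernel name (character scalar).
#' @export
match_kernel <- function(kernel = c("equal", "weighted")) {
  match.arg(kernel)
}

#' Draw fusion pairs from a cell population
#'
#' Samples `n` (unordered) pairs of distinct cells under a pairing kernel
#' without modifying the population. Used both as the simulator's
#' elementary step and for direct inspection of the kernel distribution.
#'
#' @param sizes integer vector of per-cell nuclei counts (>= 2 cells).
#' @param kernel see [match_kernel()].
#' @param n number of independent pairs to draw.
#' @return integer matrix with `n` rows and columns `a`, `b`: indices into
#'   `sizes` of the two selected cells (`a` is the first-drawn cell under
#'   the weighted kernel).
#' @examples
#' set.seed(1)
#' draw_fusion_pair(c(2, 1, 1, 1), "weighted", n = 5)
#' @export
draw_fusion_pair <- function(sizes, kernel = c("equal", "weighted"), n = 1L) {
  kernel <- match_kernel(kernel)
  if (length(sizes) < 2)
    stopf("population exhausted: need >= 2 cells to fuse (have %d)",
          length(sizes))
  if (anyNA(sizes) || any(sizes < 1) || any(sizes != as.integer(sizes)))
    stopf("cell sizes must be positive integers")
  if (!is_count(n) || n < 1) stopf("`n` must be a positive integer")
  out <- cpp_draw_pairs(as.integer(sizes), as.integer(n),
                        kernel == "weighted")
  colnames(out) <- c("a", "b")
  out
}

#' Fuse one pair of cells
#'
#' Replaces the two cells by a single cell carrying the summed nuclei
#' count. The total number of nuclei is conserved and the cell count drops
#' by one.
#'
#' @param sizes integer vector of per-cell nuclei counts.
#' @param pair length-2 vector of distinct indices into `sizes`.
#' @return the updated size vector (one element shorter).
#' @examples
#' apply_fusion(c(3, 2, 1), c(1, 2))  # -> c(5, 1)
#' @export
apply_fusion <- function(sizes, pair) {
  pair <- as.integer(pair)
  if (length(pair) != 2 || anyNA(pair) ||
      any(pair < 1) || any(pair > length(sizes)))
    stopf("`pair` must be two valid indices into `sizes`")
  if (pair[1] == pair[2])
    stopf("a cell cannot fuse with itself (identical indices)")
  sizes[pair[1]] <- sizes[pair[1]] + sizes[pair[2]]
  sizes[-pair[2]]
}

#' Run one shadow-simulation replicate
#'
#' Starts from `N` mononucleated cells and, for each time interval,
#' executes the scheduled number of fusion events under the pairing
#' kernel, recording the f4 statistic (fraction of nuclei in cells with
#' `>= threshold` nuclei) at the end of every interval -- matching the
#' end-of-interval timing of the experimental hourly annotation.
#'
#' By default the statistic is computed on the true simulated sizes; with
#' `cap_statistic = TRUE` the annotation cap is applied to the simulated
#' state as well (sensitivity analysis of the annotation distortion).
#'
#' @param N initial number of nuclei (= number of mononucleated cells at
#'   onset).
#' @param schedule a [estimate_fusion_schedule()] result or non-negative
#'   integer vector of fusion events per interval; the total must not
#'   exceed `N - 1`.
#' @param kernel see [match_kernel()].
#' @param threshold,cap,cap_statistic see [statistic_f4()].
#' @return numeric vector of f4 values, one per interval.
#' @examples
#' set.seed(7)
#' simulate_replicate(100, c(5, 5, 5), "equal")
#' @export
simulate_replicate <- function(N, schedule, kernel = c("equal", "weighted"),
                               threshold = 4L, cap = 4L,
                               cap_statistic = FALSE) {
  kernel <- match_kernel(kernel)
  counts <- as_schedule_counts(schedule)
  if (!is_count(N) || N < 2) stopf("`N` must be an integer >= 2")
  if (sum(counts) > N - 1)
    stopf("infeasible schedule: %d fusions would exhaust %d cells",
          sum(counts), N)
  cpp_simulate_replicate(as.integer(N), counts, kernel == "weighted",
                         as.integer(threshold), as.integer(cap),
                         isTRUE(cap_statistic))
}

#' Run an ensemble of shadow simulations
#'
#' Repeats [simulate_replicate()] `n_sim` times (1000 by default, the
#' standard bootstrap ensemble size for this test). Each replicate runs on
#' its own RNG substream derived from the master seed, so the ensemble is
#' reproducible and individual replicates are independent of execution
#' order.
#'
#' @inheritParams simulate_replicate
#' @param n_sim number of replicates.
#' @param seed master seed (integer).
#' @return an object of class `"fusion_ensemble"`: a list with elements
#'   `f4` (`n_sim x T` matrix of per-replicate, per-interval fractions),
#'   `kernel`, `N`, `n_sim`, `seed`, `schedule` (integer vector),
#'   `threshold`, `cap`, `cap_statistic`.
#' @examples
#' ens <- simulate_ensemble(100, c(5, 5, 5), "equal", n_sim = 50, seed = 1)
#' colMeans(ens$f4)
#' @export
simulate_ensemble <- function(N, schedule, kernel = c("equal", "weighted"),
                              n_sim = 1000L, seed, threshold = 4L, cap = 4L,
                              cap_statistic = FALSE) {
  kernel <- match_kernel(kernel)
  if (!is_count(n_sim) || n_sim < 1) stopf("`n_sim` must be >= 1")
  if (missing(seed) || !is_count(seed))
    stopf("`seed` (integer) is required for a reproducible ensemble")
  counts <- as_schedule_counts(schedule)
  if (!is_count(N) || N < 2) stopf("`N` must be an integer >= 2")
  if (sum(counts) > N - 1)
    stopf("infeasible schedule: %d fusions would exhaust %d cells",
          sum(counts), N)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_sim)
  f4 <- matrix(NA_real_, nrow = n_sim, ncol = length(counts))
  weighted <- kernel == "weighted"
  for (r in seq_len(n_sim)) {
    set.seed(rep_seeds[r])
    f4[r, ] <- cpp_simulate_replicate(as.integer(N), counts, weighted,
                                      as.integer(threshold), as.integer(cap),
                                      isTRUE(cap_statistic))
  }
  structure(list(f4 = f4, kernel = kernel, N = as.integer(N),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 schedule = counts, threshold = as.integer(threshold),
                 cap = as.integer(cap), cap_statistic = isTRUE(cap_statistic)),
            class = "fusion_ensemble")
}

#' @export
print.fusion_ensemble <- function(x, ...) {
  cat(sprintf(
    "<fusion_ensemble: %d replicates x %d intervals, kernel=%s, N=%d, seed=%d>\n",
    x$n_sim, ncol(x$f4), x$kernel, x$N, x$seed))
  cat("mean f4 per interval:",
      paste(sprintf("%.3f", colMeans(x$f4)), collapse = " "), "\n")
  invisible(x)
}

#' Export a simulation ensemble
#'
#' Writes the replicate-by-interval f4 matrix as delimited text plus a
#' JSON metadata sidecar (`<path>.meta.json`) holding the seed, kernel,
#' `N`, `n_sim`, statistic settings, the schedule, and an MD5 digest of
#' the schedule so a result can be matched to its inputs.
#'
#' @param ensemble a `fusion_ensemble`.
#' @param path output path for the matrix (CSV, one row per replicate).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fusion_ensemble"))
  m <- as.data.frame(ensemble$f4)
  names(m) <- paste0("t", seq_len(ncol(ensemble$f4)))
  write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(kernel = ensemble$kernel, N = ensemble$N,
               n_sim = ensemble$n_sim, seed = ensemble$seed,
               threshold = ensemble$threshold, cap = ensemble$cap,
               cap_statistic = ensemble$cap_statistic,
               schedule = ensemble$schedule,
               schedule_md5 = text_digest(paste(ensemble$schedule,
                                                collapse = ",")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# MD5 of a string (via a temp file; base `tools` only hashes files).
text_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
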