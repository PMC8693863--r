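#' Bootstrap comparison of observed census against a shadow ensemble
#'
#' For each annotated interval after onset, counts how many simulation
#' replicates reach or exceed the observed f4 statistic. The p-value is
#' the exceedance fraction `exceed_count / n_sim` exactly -- no
#' continuity correction -- and the null of random fusion is rejected when
#' `p <= alpha` (inclusive boundary: with 1000 replicates and
#' `alpha = 0.05`, exactly 50 exceedances is a rejection). Ties count as
#' exceedances, which makes the test conservative.
#'
#' The observed statistic is computed from the capped census (so it is a
#' lower bound whenever cells exceeded the cap); the simulated statistic
#' is whatever the ensemble recorded. p-values are reported per interval;
#' no multiple-testing correction is applied by default, but
#' `bonferroni = TRUE` adds a Bonferroni-adjusted column as a summary
#' aid.
#'
#' @param observed a [census_series()]; its first snapshot is the onset
#'   and is not tested.
#' @param ensemble a [simulate_ensemble()] result whose interval count
#'   equals `nrow(observed) - 1`.
#' @param alpha rejection threshold (default 0.05).
#' @param threshold nuclei threshold for the observed statistic
#'   (default 4).
#' @param bonferroni add a `p_adjusted` column (Bonferroni across the
#'   tested intervals).
#' @return a data frame of class `"fusion_test"` with columns `t`,
#'   `observed_f4`, `exceed_count`, `p_value`, `reject` (and optionally
#'   `p_adjusted`), and attributes `alpha`, `n_sim`, `kernel`.
#' @examples
#' obs <- census_series(data.frame(t = 0:2, c1 = c(60, 48, 40),
#'                                 c2 = c(0, 4, 6), c3 = c(0, 0, 0),
#'                                 c4 = c(0, 1, 2)))
#' sched <- estimate_fusion_schedule(obs)
#' ens <- simulate_ensemble(60, sched, "equal", n_sim = 200, seed = 4)
#' bootstrap_pvalues(obs, ens)
#' @export
bootstrap_pvalues <- function(observed, ensemble, alpha = 0.05,
                              threshold = 4L, bonferroni = FALSE) {
  if (!inherits(observed, "census_series")) observed <- census_series(observed)
  stopifnot(inherits(ensemble, "fusion_ensemble"))
  if (ensemble$n_sim < 1) stopf("ensemble has no replicates")
  n_int <- ncol(ensemble$f4)
  if (n_int != nrow(observed) - 1)
    stopf("ensemble covers %d intervals but the census has %d tested intervals",
          n_int, nrow(observed) - 1)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stopf("`alpha` must be in [0, 1]")
  obs_f4 <- vapply(seq_len(n_int) + 1L, function(i) {
    statistic_f4(series_snapshot(observed, i), threshold = threshold)
  }, numeric(1))
  exceed <- vapply(seq_len(n_int), function(j) {
    sum(ensemble$f4[, j] >= obs_f4[j])
  }, integer(1))
  p <- exceed / ensemble$n_sim
  res <- data.frame(t = observed$t[-1], observed_f4 = obs_f4,
                    exceed_count = exceed, p_value = p,
                    reject = p <= alpha)
  if (isTRUE(bonferroni))
    res$p_adjusted <- p.adjust(p, method = "bonferroni")
  structure(res, alpha = alpha, n_sim = ensemble$n_sim,
            kernel = ensemble$kernel,
            class = c("fusion_test", "data.frame"))
}

#' @export
print.fusion_test <- function(x, ...) {
  cat(sprintf("<fusion_test: kernel=%s, n_sim=%d, alpha=%g, %d/%d intervals rejected>\n",
              attr(x, "kernel"), attr(x, "n_sim"), attr(x, "alpha"),
              sum(x$reject), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Test an observed census against both pairing kernels
#'
#' The full shadow analysis: estimate the fusion schedule from the census,
#' simulate an ensemble under the equal and the size-weighted kernel, and
#' compute per-interval bootstrap p-values for each. The two kernels run
#' on independent RNG substreams derived from the master seed, so results
#' for one kernel are unchanged by adding or dropping the other.
#'
#' @inheritParams bootstrap_pvalues
#' @param n_sim replicates per kernel (default 1000).
#' @param seed master seed.
#' @param N initial nuclei count for the simulations; defaults to the
#'   annotated nuclei total of the onset snapshot (exact when the
#'   experiment starts from mononucleated cells only).
#' @param kernels which kernels to run.
#' @param cap_statistic apply the annotation cap to simulated states (see
#'   [simulate_replicate()]).
#' @return named list of `"fusion_test"` objects (one per kernel) with
#'   attributes `schedule` (the estimated [estimate_fusion_schedule()])
#'   and `N`.
#' @examples
#' obs <- census_series(data.frame(t = 0:2, c1 = c(60, 48, 40),
#'                                 c2 = c(0, 4, 6), c3 = c(0, 0, 0),
#'                                 c4 = c(0, 1, 2)))
#' run_both_kernels(obs, n_sim = 100, seed = 11)
#' @export
run_both_kernels <- function(observed, n_sim = 1000L, seed, alpha = 0.05,
                             N = NULL, kernels = c("equal", "weighted"),
                             threshold = 4L, cap_statistic = FALSE) {
  if (!inherits(observed, "census_series")) observed <- census_series(observed)
  if (missing(seed) || !is_count(seed))
    stopf("`seed` (integer) is required for a reproducible run")
  kernels <- match.arg(kernels, c("equal", "weighted"), several.ok = TRUE)
  schedule <- estimate_fusion_schedule(observed)
  if (is.null(N)) N <- total_nuclei(series_snapshot(observed, 1))
  if (!is_count(N) || N < 2)
    stopf("`N` must be an integer >= 2 (onset snapshot may be empty)")
  out <- lapply(kernels, function(k) {
    ens <- simulate_ensemble(N, schedule, k, n_sim = n_sim,
                             seed = derive_seed(seed, k),
                             threshold = threshold,
                             cap = attr(observed, "cap"),
                             cap_statistic = cap_statistic)
    bootstrap_pvalues(observed, ens, alpha = alpha, threshold = threshold)
  })
  names(out) <- kernels
  attr(out, "schedule") <- schedule
  attr(out, "N") <- as.integer(N)
  out
}

#' Export a bootstrap test result
#'
#' Writes `t,observed_f4,exceed_count,p_value,reject` as delimited text.
#'
#' @param result a `"fusion_test"`.
#' @param path output path.
#' @export
write_test_result <- function(result, path) {
  stopifnot(inherits(result, "fusion_test"))
  write.table(as.data.frame(result), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
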