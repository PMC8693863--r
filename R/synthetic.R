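#' Configuration for a synthetic fusion experiment
#'
#' Describes a ground-truth fusion trajectory to generate: the pairing
#' regime, the population size, the interval count, and the expected
#' number of fusion events per interval. Three regimes are available:
#'
#' * `"equal"` -- every pair of cells equally likely to fuse (the pure
#'   random null);
#' * `"weighted"` -- cells selected with probability proportional to
#'   their nuclei count (size-biased null);
#' * `"founder"` -- directed growth: the acceptor cell is drawn with
#'   weight `founder_bias` if multinucleated and 1 if mononucleated, and
#'   the donor is drawn uniformly among mononucleated cells (falling back
#'   to uniform pairing among the remaining cells if no mononucleated
#'   donor is available). This emulates nascent myotubes that recruit
#'   surrounding myoblasts, the biological alternative to stochastic
#'   fusion. With `founder_bias = 0` multinucleated acceptors are never
#'   chosen, so pairing is equal among the mononucleated cells.
#'
#' Defaults emulate an hourly time-lapse of a well-populated field:
#' `N = 1000` nuclei followed over `T = 15` hourly intervals with an
#' expected 15 fusion events per interval.
#'
#' @param regime `"equal"`, `"weighted"` or `"founder"`.
#' @param N initial nuclei count; every cell starts mononucleated.
#' @param T number of time intervals.
#' @param rate expected fusion events per interval; scalar or vector of
#'   length `T`.
#' @param founder_bias acceptor weight of a multinucleated cell in the
#'   founder regime (`>= 0`; mononucleated weight is 1).
#' @param cap annotation cap applied to the observed census.
#' @param seed integer seed; the experiment is fully reproducible from it.
#' @param count_model `"poisson"` (event count per interval is Poisson
#'   with mean `rate`) or `"deterministic"` (`round(rate)` events
#'   exactly, useful for exact estimator checks).
#' @return a list of class `"regime_config"`.
#' @export
regime_config <- function(regime = c("equal", "weighted", "founder"),
                          N = 1000L, T = 15L, rate = 15,
                          founder_bias = 50, cap = 4L, seed,
                          count_model = c("poisson", "deterministic")) {
  regime <- match.arg(regime)
  count_model <- match.arg(count_model)
  if (!is_count(N) || N < 2) stopf("`N` must be an integer >= 2")
  if (!is_count(T) || T < 1) stopf("`T` must be a positive integer")
  if (missing(seed) || !is_count(seed)) stopf("`seed` (integer) is required")
  if (!is.numeric(rate) || anyNA(rate) || any(rate < 0))
    stopf("`rate` must be non-negative")
  if (!length(rate) %in% c(1L, T))
    stopf("`rate` must have length 1 or T (%d)", T)
  if (!is.numeric(founder_bias) || founder_bias < 0)
    stopf("`founder_bias` must be >= 0")
  if (!is_count(cap) || cap < 2) stopf("`cap` must be an integer >= 2")
  structure(list(regime = regime, N = as.integer(N), T = as.integer(T),
                 rate = rep_len(as.numeric(rate), T),
                 founder_bias = as.numeric(founder_bias),
                 cap = as.integer(cap), seed = as.integer(seed),
                 count_model = count_model),
            class = "regime_config")
}

# One fusion event under a generation regime; returns indices c(acceptor,
# donor) into `sizes`.
draw_regime_pair <- function(sizes, regime, founder_bias) {
  m <- length(sizes)
  if (regime == "equal") {
    return(sample.int(m, 2L))
  }
  if (regime == "weighted") {
    a <- sample.int(m, 1L, prob = sizes)
    rest <- seq_len(m)[-a]
    b <- if (length(rest) == 1L) rest
         else rest[sample.int(m - 1L, 1L, prob = sizes[rest])]
    return(c(a, b))
  }
  # founder: acceptor weight founder_bias if multinucleated else 1;
  # donor uniform among mononucleated cells, fallback uniform among rest
  w <- ifelse(sizes > 1L, founder_bias, 1)
  if (all(w == 0)) w[] <- 1  # founder_bias = 0 with no mononucleated cells
  a <- sample.int(m, 1L, prob = w)
  donors <- which(sizes == 1L)
  donors <- donors[donors != a]
  if (length(donors) == 0L) donors <- seq_len(m)[-a]
  b <- if (length(donors) == 1L) donors else donors[sample.int(length(donors), 1L)]
  c(a, b)
}

#' Generate a ground-truth synthetic fusion experiment
#'
#' Simulates a fusion-only trajectory (no division, death, or field exit)
#' under the configured regime and returns the true per-interval cell-size
#' states, the capped census a microscopist would have annotated, and the
#' full event log -- so the estimator, the shadow simulator, and the
#' bootstrap test can all be validated against known ground truth.
#'
#' Per interval the realized event count is Poisson (or deterministic, see
#' [regime_config()]); events that would exhaust the population (more than
#' `N - 1` cumulative fusions) are dropped with a warning.
#'
#' @param config a [regime_config()].
#' @return a list of class `"synthetic_experiment"` with elements
#'   `config`, `states` (list of `T + 1` integer size vectors, onset
#'   included), `observed` (a [census_series()] of `T + 1` capped
#'   snapshots), `events` (data frame `t, acceptor_size, donor_size`,
#'   sizes as of just before the event), and `n_dropped`.
#' @examples
#' exp <- generate_experiment(regime_config("equal", N = 200, T = 5,
#'                                          rate = 8, seed = 42))
#' exp$observed
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "regime_config"))
  set.seed(config$seed)
  sizes <- rep(1L, config$N)
  states <- vector("list", config$T + 1L)
  states[[1L]] <- sizes
  snaps <- vector("list", config$T + 1L)
  snaps[[1L]] <- bin_sizes(sizes, cap = config$cap, t_index = 0L)
  ev_t <- integer(0); ev_a <- integer(0); ev_d <- integer(0)
  dropped <- 0L
  for (t in seq_len(config$T)) {
    k <- if (config$count_model == "poisson") rpois(1L, config$rate[t])
         else as.integer(round(config$rate[t]))
    avail <- length(sizes) - 1L
    if (k > avail) {
      dropped <- dropped + (k - avail)
      k <- avail
    }
    for (e in seq_len(k)) {
      pair <- draw_regime_pair(sizes, config$regime, config$founder_bias)
      ev_t <- c(ev_t, t)
      ev_a <- c(ev_a, sizes[pair[1L]])
      ev_d <- c(ev_d, sizes[pair[2L]])
      sizes <- apply_fusion(sizes, pair)
    }
    states[[t + 1L]] <- sizes
    snaps[[t + 1L]] <- bin_sizes(sizes, cap = config$cap, t_index = t)
  }
  if (dropped > 0L)
    warnf("dropped %d fusion event(s): population exhausted", dropped)
  structure(list(config = config, states = states,
                 observed = census_series(snaps),
                 events = data.frame(t = ev_t, acceptor_size = ev_a,
                                     donor_size = ev_d),
                 n_dropped = dropped),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment: regime=%s, N=%d, T=%d, %d fusion events, seed=%d>\n",
    x$config$regime, x$config$N, x$config$T, nrow(x$events), x$config$seed))
  invisible(x)
}

#' Ground-truth fusion schedule of a synthetic experiment
#'
#' Tabulates the realized fusion events per interval from the event log,
#' in the same `"fusion_schedule"` shape as [estimate_fusion_schedule()]
#' so the two can be compared directly.
#'
#' @param experiment a [generate_experiment()] result.
#' @return a `"fusion_schedule"` data frame (here `raw == n_fusion`, both
#'   the true realized counts).
#' @export
truth_schedule <- function(experiment) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  counts <- tabulate(experiment$events$t, nbins = experiment$config$T)
  new_fusion_schedule(t = seq_len(experiment$config$T), raw = counts,
                      n_fusion = counts, cap = experiment$config$cap)
}

#' Write a synthetic experiment bundle
#'
#' Writes the capped census (`census.csv`, [write_census_table()] format),
#' the event log (`events.csv`: `t,acceptor_size,donor_size`), and a JSON
#' config manifest (`config.json`) into a directory.
#'
#' @param experiment a `"synthetic_experiment"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_census_table(experiment$observed, file.path(dir, "census.csv"))
  write.table(experiment$events, file.path(dir, "events.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(experiment$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
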