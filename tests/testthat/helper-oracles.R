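# Shared oracles and fixture builders. Everything here is independent of
# the package's sampling code paths: enumeration and closed forms only.

# All multisets of positive integers (as sorted vectors) with part count
# in [min_cells, max_cells] and total in [2, max_total].
enumerate_states <- function(max_cells = 6, max_total = 10, min_cells = 2) {
  parts <- function(n, k_max, largest) {
    # partitions of n into at most k_max parts, each <= largest
    if (n == 0) return(list(integer(0)))
    if (k_max == 0) return(list())
    out <- list()
    for (p in seq_len(min(n, largest))) {
      for (rest in parts(n - p, k_max - 1, p))
        out <- c(out, list(c(p, rest)))
    }
    out
  }
  states <- list()
  for (s in 2:max_total)
    states <- c(states, parts(s, max_cells, s))
  Filter(function(p) length(p) >= min_cells, states)
}

# Exact probability of each unordered index pair {i, j} under a kernel.
# Rows: i, j (i < j), prob.
exact_pair_probs <- function(sizes, kernel) {
  m <- length(sizes)
  S <- sum(sizes)
  pairs <- utils::combn(m, 2)
  prob <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (kernel == "equal") {
      1 / choose(m, 2)
    } else {
      sizes[i] / S * sizes[j] / (S - sizes[i]) +
        sizes[j] / S * sizes[i] / (S - sizes[j])
    }
  })
  data.frame(i = pairs[1, ], j = pairs[2, ], prob = prob)
}

# Empirical unordered-pair frequencies from n kernel draws.
empirical_pair_freqs <- function(sizes, kernel, n) {
  d <- draw_fusion_pair(sizes, kernel, n = n)
  lo <- pmin(d[, 1], d[, 2])
  hi <- pmax(d[, 1], d[, 2])
  key <- (lo - 1L) * length(sizes) + hi  # unique small-int code per pair
  counts <- tabulate(key, nbins = length(sizes)^2)
  ex <- exact_pair_probs(sizes, kernel)
  ex$freq <- counts[(ex$i - 1L) * length(sizes) + ex$j] / n
  ex
}

# A small valid census series fixture: closed population, fusion only.
toy_series <- function() {
  census_series(data.frame(
    t  = 0:3,
    c1 = c(60L, 52L, 47L, 38L),
    c2 = c(0L, 4L, 5L, 6L),
    c3 = c(0L, 0L, 1L, 2L),
    c4 = c(0L, 0L, 0L, 1L)))
}

# Generate equal-regime experiments until `n` of them never exceed the cap
# (for exact-estimator checks); returns a list of experiments.
capped_free_experiments <- function(n, N = 400, T = 6, rate = 6,
                                    cap = 4, seed0 = 1) {
  out <- vector("list", n)
  got <- 0
  seed <- seed0
  while (got < n) {
    exp <- generate_experiment(regime_config(
      "equal", N = N, T = T, rate = rate, cap = cap, seed = seed,
      count_model = "deterministic"))
    if (max(unlist(exp$states)) <= cap) {
      got <- got + 1
      out[[got]] <- exp
    }
    seed <- seed + 1
  }
  out
}
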