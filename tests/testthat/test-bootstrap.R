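# A hand-built ensemble makes the exceedance arithmetic fully transparent.
fake_ensemble <- function(f4_matrix, kernel = "equal") {
  structure(list(f4 = f4_matrix, kernel = kernel, N = 1000L,
                 n_sim = nrow(f4_matrix), seed = 0L,
                 schedule = rep(1L, ncol(f4_matrix)), threshold = 4L,
                 cap = 4L, cap_statistic = FALSE),
            class = "fusion_ensemble")
}

test_that("p-values are exact exceedance fractions with inclusive ties", {
  # 2 intervals observed; f4_obs = 0 then 4/60
  obs <- census_series(data.frame(t = 0:2, c1 = c(60, 60, 56), c2 = 0,
                                  c3 = 0, c4 = c(0, 0, 1)))
  m <- cbind(c(0, 0, 0, 0), c(0, 4 / 60, 0.5, 0.01))
  res <- bootstrap_pvalues(obs, fake_ensemble(m))
  # observed 0 is matched (tie) by every replicate -> p = 1
  expect_equal(res$p_value[1], 1)
  # ties count as exceeding: 4/60 and 0.5 both >= 4/60
  expect_equal(res$exceed_count[2], 2L)
  expect_equal(res$p_value[2], 0.5)
  expect_identical(res$p_value, res$exceed_count / 4)
})

test_that("the 50-out-of-1000 boundary is an inclusive rejection", {
  obs <- census_series(data.frame(t = 0:1, c1 = 56, c2 = 0, c3 = 0,
                                  c4 = c(1, 1)))
  f4_obs <- 4 / 60
  make <- function(n_exceed) {
    fake_ensemble(matrix(c(rep(1, n_exceed), rep(0, 1000 - n_exceed)),
                         ncol = 1))
  }
  at_50 <- bootstrap_pvalues(obs, make(50))
  expect_equal(at_50$p_value, 0.05)
  expect_true(at_50$reject)
  at_51 <- bootstrap_pvalues(obs, make(51))
  expect_false(at_51$reject)
  at_0 <- bootstrap_pvalues(obs, make(0))
  expect_equal(at_0$p_value, 0)
  expect_true(at_0$reject)
})

test_that("mismatched dimensions and empty ensembles are rejected", {
  obs <- toy_series()
  short <- fake_ensemble(matrix(0, nrow = 5, ncol = 2))
  expect_error(bootstrap_pvalues(obs, short), "intervals")
})

test_that("p-values live on the 1/n_sim grid and are audit-recomputable", {
  exp <- generate_experiment(regime_config("equal", N = 300, T = 6, rate = 10,
                                           seed = 55))
  sched <- estimate_fusion_schedule(exp$observed)
  ens <- simulate_ensemble(300, sched, "equal", n_sim = 123, seed = 77)
  res <- bootstrap_pvalues(exp$observed, ens)
  expect_true(all(res$p_value %in% ((0:123) / 123)))
  for (j in seq_len(nrow(res)))
    expect_equal(res$exceed_count[j],
                 sum(ens$f4[, j] >= res$observed_f4[j]))
  # optional Bonferroni summary column
  resb <- bootstrap_pvalues(exp$observed, ens, bonferroni = TRUE)
  expect_equal(resb$p_adjusted, pmin(1, res$p_value * nrow(res)))
})

test_that("run_both_kernels is deterministic and kernel substreams are decoupled", {
  exp <- generate_experiment(regime_config("equal", N = 250, T = 5, rate = 10,
                                           seed = 60))
  r1 <- run_both_kernels(exp$observed, n_sim = 150, seed = 99)
  r2 <- run_both_kernels(exp$observed, n_sim = 150, seed = 99)
  expect_identical(r1, r2)
  expect_named(r1, c("equal", "weighted"))
  # running one kernel alone reproduces its half of the joint run
  r_eq <- run_both_kernels(exp$observed, n_sim = 150, seed = 99,
                           kernels = "equal")
  expect_identical(r_eq$equal, r1$equal)
  # the estimated schedule rides along for audit
  expect_s3_class(attr(r1, "schedule"), "fusion_schedule")
})

test_that("founder-bias sensitivity: stronger bias lowers late p-values on average", {
  betas <- c(0, 10, 50)
  mean_final_p <- vapply(betas, function(b) {
    ps <- vapply(1:8, function(i) {
      exp <- suppressWarnings(generate_experiment(regime_config(
        "founder", N = 300, T = 8, rate = 12, founder_bias = b,
        seed = 700 + i)))  # common seeds across betas
      res <- suppressWarnings(run_both_kernels(exp$observed, n_sim = 200,
                                               seed = 800 + i,
                                               kernels = "equal"))
      res$equal$p_value[8]
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(all(diff(mean_final_p) <= 0))
})

test_that("test results export in the documented column layout", {
  exp <- generate_experiment(regime_config("equal", N = 200, T = 4, rate = 8,
                                           seed = 3))
  res <- run_both_kernels(exp$observed, n_sim = 50, seed = 5,
                          kernels = "equal")
  f <- withr::local_tempfile(fileext = ".csv")
  write_test_result(res$equal, f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("t", "observed_f4", "exceed_count", "p_value", "reject"))
  expect_equal(back$p_value, res$equal$p_value)
})
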