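test_that("fusion index gates on marker positivity over all nuclei", {
  mono <- data.frame(nuclei_count = rep(1, 8), myhc = c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(fusion_index(mono), 0)
  mixed <- data.frame(nuclei_count = c(4, rep(1, 6)),
                      myhc = c(1, rep(0, 6)))
  expect_equal(fusion_index(mixed), 40)  # 4 of 10 nuclei
  # marker-negative binucleated cell is excluded by the gate
  neg <- data.frame(nuclei_count = c(2, 1, 1), myhc = c(0, 1, 1))
  expect_equal(fusion_index(neg), 0)
  expect_error(fusion_index(data.frame(nuclei_count = integer(0),
                                       myhc = logical(0))), "empty")
})

test_that("stratified nuclei fractions partition all nuclei", {
  out <- stratified_fusion_index(data.frame(nuclei_count = c(1, 1, 2)),
                                 "hourly")
  expect_equal(unname(out), c(0.5, 0.5, 0, 0))
  out <- stratified_fusion_index(data.frame(nuclei_count = 12), "endpoint")
  expect_equal(unname(out), c(0, 0, 0, 1))
  set.seed(31)
  for (i in 1:20) {
    cells <- data.frame(nuclei_count = sample(1:15, 40, replace = TRUE))
    for (preset in c("hourly", "endpoint"))
      expect_equal(sum(stratified_fusion_index(cells, preset)), 1)
  }
  expect_error(
    stratified_fusion_index(data.frame(nuclei_count = 1),
                            data.frame(lo = c(1, 3), hi = c(1, Inf))),
    "contiguous")
  expect_error(stratified_fusion_index(data.frame(nuclei_count = 1),
                                       "weekly"), "preset")
})

test_that("stratified top bin agrees with the f4 statistic across modules", {
  set.seed(32)
  for (i in 1:10) {
    sizes <- sample(1:9, 30, replace = TRUE)
    cells <- data.frame(nuclei_count = sizes, myhc = TRUE)
    expect_equal(unname(stratified_fusion_index(cells, "hourly")["4plus"]),
                 statistic_f4(sizes))
    # fusion index == 100 * statistic with threshold 2 when all cells MyHC+
    expect_equal(fusion_index(cells),
                 100 * statistic_f4(sizes, threshold = 2))
  }
})

test_that("marker fractions support pooled and per-frame weighting", {
  nuc <- data.frame(frame = rep(1:2, c(20, 80)),
                    myog = c(rep(1, 10), rep(0, 10), rep(1, 30), rep(0, 50)))
  expect_equal(marker_positive_fraction(nuc, "myog"), 40)
  per <- marker_positive_fraction(nuc, "myog", per_frame = TRUE)
  expect_equal(unname(per), c(50, 37.5))
  expect_equal(marker_positive_fraction(data.frame(frame = 1, ki67 = rep(0, 50)),
                                        "ki67"), 0)
  expect_error(marker_positive_fraction(nuc, "ph3"), "unknown marker")
})

test_that("migration rate is displacement-based, gap-aware, and rigid-motion invariant", {
  still <- data.frame(nucleus_id = "a", t = 0:3, x_um = 1, y_um = 2)
  expect_equal(migration_rate(still, 5)$cohort_mean, 0)

  one <- data.frame(nucleus_id = "b", t = 0:1, x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(migration_rate(one, 5)$cohort_mean, 1)  # 5 um over 5 min

  # a skipped frame splits the track: the 0->2 jump is never used
  gap <- data.frame(nucleus_id = "c", t = c(0, 1, 3, 4),
                    x_um = c(0, 1, 50, 51), y_um = 0)
  mr <- migration_rate(gap, 10)
  expect_equal(mr$per_track$n_steps, 2)
  expect_equal(mr$cohort_mean, 0.1)

  # single-sample tracks are excluded with a warning
  mix <- rbind(one, data.frame(nucleus_id = "d", t = 0, x_um = 0, y_um = 0))
  expect_warning(mr2 <- migration_rate(mix, 5), "excluded 1 track")
  expect_equal(mr2$cohort_mean, 1)
  expect_error(suppressWarnings(
    migration_rate(mix[3, ], 5)), "no usable tracks")

  # invariance under global translation + rotation
  set.seed(33)
  tr <- data.frame(nucleus_id = rep(1:3, each = 5), t = rep(0:4, 3),
                   x_um = rnorm(15), y_um = rnorm(15))
  th <- 0.77
  rot <- transform(tr,
                   x_um = cos(th) * x_um - sin(th) * y_um + 12,
                   y_um = sin(th) * x_um + cos(th) * y_um - 3)
  expect_equal(migration_rate(rot, 5)$cohort_mean,
               migration_rate(tr, 5)$cohort_mean)
})

test_that("annotation tables read from disk with validation", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "cells.csv")
  writeLines(c("frame,cell_id,nuclei_count,myhc", "1,a,4,1", "1,b,1,0"), cf)
  cells <- read_cell_table(cf)
  expect_equal(fusion_index(cells), 80)
  nf <- file.path(d, "nuclei.csv")
  writeLines(c("frame,nucleus_id,myog", "1,n1,1", "1,n2,0"), nf)
  expect_equal(marker_positive_fraction(read_nucleus_table(nf), "myog"), 50)
  tf <- file.path(d, "tracks.csv")
  writeLines(c("nucleus_id,t,x_um,y_um", "n1,0,0,0", "n1,1,3,4"), tf)
  expect_equal(migration_rate(read_track_table(tf), 5)$cohort_mean, 1)
})
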