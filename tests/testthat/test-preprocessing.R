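test_that("TTD categorization uses half-open bins with boundary -> upper bin", {
  expect_equal(categorize_ttd(7.15), 0)       # the typical (median-like) case
  expect_equal(categorize_ttd(30), 1)
  expect_equal(categorize_ttd(120), 3)
  expect_equal(categorize_ttd(121), 3)
  expect_equal(categorize_ttd(c(29.999, 30, 59.9, 60, 119, 120, 1e6)),
               c(0, 1, 1, 2, 2, 3, 3))
  # extended bin edges give 6 categories
  ext <- c(30, 60, 120, 180, 240)
  expect_equal(categorize_ttd(c(10, 150, 200, 240, 500), ext),
               c(0, 3, 4, 5, 5))
  expect_error(categorize_ttd(0), "positive")
  expect_error(categorize_ttd(-5), "positive")
  expect_error(categorize_ttd(10, c(60, 30)), "increasing")
})

test_that("label counts always sum to the cohort size (label conservation)", {
  set.seed(4)
  for (i in 1:5) {
    ttd <- rlnorm(200, 2, 3)
    edges <- sort(runif(sample(1:5, 1), 1, 500))
    expect_equal(sum(tabulate(categorize_ttd(ttd, edges) + 1L,
                              length(edges) + 1L)), 200)
  }
})

test_that("imputation is forward-fill, then backward-fill, then train mean", {
  co <- small_cohort()
  stats <- normalization_stats(co)
  # channel observed (NA, 4, NA, 6) over 4 times -> (4, 4, 4, 6)
  s <- mk_series(c(-40, -30, -20, -10),
                 cbind(c(NA, 4, NA, 6), c(1, 1, 1, 1), c(NA, NA, NA, NA)),
                 cbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(0, 0, 0, 0)))
  st2 <- stats
  st2$channel$mean[3] <- 2.5
  imp <- impute_series(s, st2)
  expect_equal(unname(imp$values[, 1]), c(4, 4, 4, 6))
  # never-observed channel: filled with the training mean
  expect_equal(unname(imp$values[, 3]), rep(2.5, 4))
  # fully observed channel unchanged
  expect_equal(unname(imp$values[, 2]), rep(1, 4))
  # masks untouched and idempotence
  expect_equal(imp$masks, s$masks)
  expect_equal(impute_series(imp, st2), imp)
})

test_that("z-scoring maps train mean to 0, mean + sd to 1, and inverts", {
  co <- small_cohort()
  stats <- normalization_stats(co)
  mu <- stats$channel$mean[1]; sdv <- stats$channel$sd[1]
  s <- mk_series(c(-10, -5), cbind(c(mu, mu + sdv), c(95, 95), c(5, 5)))
  z <- normalize_series(impute_series(s, stats), stats)
  expect_equal(unname(z$values[, 1]), c(0, 1))
  back <- denormalize_series(z, stats)
  expect_equal(back$values, impute_series(s, stats)$values)
})

test_that("binary channels are never z-scored", {
  v <- ttd_vocabulary(c("pulse", "flag"), c("age"),
                      c("continuous", "binary"), c("continuous"))
  rec <- patient_record("p", c(age = 50),
                        longitudinal_series(c(-10, -5),
                          matrix(c(80, 90, 1, 0), 2, 2,
                                 dimnames = list(NULL, c("pulse", "flag"))),
                          matrix(1, 2, 2)), 10, 2018)
  co <- ttd_cohort(list(rec), v)
  stats <- normalization_stats(co)
  prep <- prepare_cohort(co, stats)
  expect_equal(prep$patients[[1]]$X[, 2], c(1, 0))
})

test_that("degenerate channels get sd 1 with a log message", {
  co <- small_cohort()
  # gcs for patient c is a single value; make a constant channel instead
  rec <- mk_record("e", c(-20, -10), rbind(c(7, NA, NA), c(7, NA, NA)))
  expect_message(stats <- normalization_stats(ttd_cohort(list(rec), small_vocab())),
                 "degenerate")
  expect_true(all(stats$channel$sd >= 1))
})

test_that("temporal split respects the cutoff with 2021 in the test side", {
  co <- small_cohort()  # years 2018, 2019, 2022, 2022
  sp <- temporal_split(co, 2021)
  expect_equal(length(sp$train), 2)
  expect_equal(length(sp$test), 2)
  expect_true(all(cohort_years(sp$train) < 2021))
  expect_true(all(cohort_years(sp$test) >= 2021))
  # exhaustive and disjoint
  expect_setequal(c(cohort_ids(sp$train), cohort_ids(sp$test)), cohort_ids(co))
  # a patient from exactly 2021 goes to test
  co2 <- ttd_cohort(c(co$records,
                      list(mk_record("y21", -10, rbind(c(80, 95, 6)),
                                     year = 2021))), small_vocab())
  expect_true("y21" %in% cohort_ids(temporal_split(co2)$test))
  expect_error(temporal_split(co, 2010), "training side is empty")
  expect_error(temporal_split(co, 2030), "test side is empty")
})

test_that("history truncation drops the final horizon and flags emptiness", {
  s <- mk_series(c(-800, -700, -100),
                 cbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # a 12 h horizon keeps only data already available 720 min before
  # extubation: -700 (11.7 h before) is inside the final horizon
  expect_equal(truncate_history(s, 720)$times, -800)
  expect_equal(truncate_history(s, 600)$times, c(-800, -700))
  # horizon longer than the full history leaves nothing
  expect_null(truncate_history(s, 1000))
  # a tiny horizon keeps everything
  expect_equal(truncate_history(s, 0.001)$times, s$times)
})

test_that("prepared patients are fully defined with capped gaps and labels", {
  st <- default_study()
  p <- st$train$patients[[1]]
  expect_false(anyNA(p$X))
  expect_true(all(p$dt_hours >= 0 & p$dt_hours <= 24))
  expect_equal(p$dt_hours[1], 0)
  expect_true(all(st$train$labels %in% 0:3))
  # truncation inside prepare_cohort drops emptied patients with a warning
  co <- small_cohort()
  stats <- normalization_stats(co)
  expect_warning(pr <- prepare_cohort(co, stats, horizon_min = 70),
                 "dropped")
  expect_setequal(pr$ids, c("a", "d"))  # only a and d have data before -70
})

test_that("preprocessing statistics depend on the training split only", {
  co <- small_cohort()
  sp <- temporal_split(co, 2021)
  stats_tr <- normalization_stats(sp$train)
  # train patients a, b: pulse observations 80, 110, 70, 75
  expect_equal(stats_tr$channel$mean[stats_tr$channel$name == "pulse"],
               mean(c(80, 110, 70, 75)))
  # a test-only patient imputed with the *train* mean, not its own cohort's
  rec <- mk_record("z", c(-30, -20), rbind(c(NA, 99, NA), c(NA, 98, NA)),
                   year = 2022)
  prep <- prepare_cohort(ttd_cohort(list(rec), small_vocab()), stats_tr,
                         normalize = FALSE)
  expect_equal(prep$patients[[1]]$X[, 1], rep(mean(c(80, 110, 70, 75)), 2))
})
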