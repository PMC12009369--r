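test_that("series and record constructors enforce their invariants", {
  expect_error(mk_series(c(-5, -10), rbind(c(1, 2, 3), c(1, 2, 3))),
               "strictly increasing")
  expect_error(mk_series(c(-10, 5), rbind(c(1, 2, 3), c(1, 2, 3))), "<= 0")
  expect_error(mk_series(-10, rbind(c(NA, NA, NA))), "at least one observed")
  expect_error(mk_record("x", -10, rbind(c(80, 95, 6)), ttd = 0), "positive")
  expect_error(mk_record("x", -10, rbind(c(80, 95, 6)), ttd = -3), "positive")
  s <- mk_series(c(-10, -5), rbind(c(80, NA, 6), c(NA, 92, NA)))
  expect_equal(s$masks, matrix(c(1, 0, 0, 1, 1, 0), 2, 3,
                               dimnames = list(NULL, c("pulse", "spo2", "gcs"))))
})

test_that("cohorts reject duplicate ids and mismatched vocabularies", {
  r <- mk_record("a", -10, rbind(c(80, 95, 6)))
  expect_error(ttd_cohort(list(r, r), small_vocab()), "duplicated patient_id")
  expect_error(ttd_cohort(list(r), default_vocabulary()), "channels")
})

test_that("write_cohort / read_cohort round trip is the identity", {
  sim <- simulate_cohort(sim_config(n_patients = 10, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  expect_true(all(file.exists(file.path(dir, c("static.csv", "longitudinal.csv",
                                               "outcomes.csv", "vocabulary.yaml")))))
  back <- read_cohort_dir(dir)
  expect_setequal(cohort_ids(back), cohort_ids(sim$cohort))
  for (id in cohort_ids(sim$cohort)) {
    a <- sim$cohort[id]$records[[1]]
    b <- back[id]$records[[1]]
    expect_equal(b$series$times, a$series$times)
    expect_equal(b$series$masks, a$series$masks, ignore_attr = TRUE)
    obs <- a$series$masks == 1
    expect_equal(b$series$values[obs], a$series$values[obs])
    expect_equal(b$static, a$static)
    expect_equal(b$ttd_minutes, a$ttd_minutes)
    expect_equal(b$era_year, a$era_year)
  }
  expect_error(write_cohort(ttd_cohort(list(), small_vocab()), dir), "empty")
})

test_that("unicode patient ids survive the round trip", {
  rec <- mk_record("pätient-九", c(-10, -5),
                   rbind(c(80, 95, 6), c(82, NA, NA)))
  dir <- withr::local_tempdir()
  write_cohort(ttd_cohort(list(rec), small_vocab()), dir)
  expect_identical(cohort_ids(read_cohort_dir(dir)), "pätient-九")
})

test_that("read_cohort joins, sorts, deduplicates and warns as specified", {
  dir <- withr::local_tempdir()
  lon <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p3", "p1"),
    time_min = c(-5, -10, -5, -20, -7, -5),
    variable = c("pulse", "pulse", "spo2", "gcs", "pulse", "pulse"),
    value = c(80, 75, 95, 7, 90, 85))
  sta <- data.frame(patient_id = c("p1", "p2", "p3"),
                    variable = "age", value = c(60, 70, 50))
  out <- data.frame(patient_id = c("p1", "p2"), ttd_minutes = c(12, 45),
                    era_year = c(2018, 2022))
  write.csv(lon, file.path(dir, "l.csv"), row.names = FALSE)
  write.csv(sta, file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(out, file.path(dir, "o.csv"), row.names = FALSE)

  expect_warning(
    expect_message(
      co <- read_cohort(file.path(dir, "s.csv"), file.path(dir, "l.csv"),
                        file.path(dir, "o.csv"), small_vocab()),
      "duplicated"),
    "without outcome")
  # 3 patients in the files, only 2 with outcomes
  expect_equal(length(co), 2)
  p1 <- co["p1"]$records[[1]]
  # time-sorted rows
  expect_equal(p1$series$times, c(-10, -5))
  # duplicate (p1, -5, pulse): last row (85) wins
  expect_equal(unname(p1$series$values[2, "pulse"]), 85)
  # spo2 observed once -> exactly one mask 1 in that column
  expect_equal(sum(p1$series$masks[, "spo2"]), 1)
  # statics joined
  expect_equal(unname(p1$static["age"]), 60)
  expect_true(is.na(p1$static["bmi"]))
})

test_that("unknown variables are rejected with the offending row named", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(patient_id = "p1", time_min = -5,
                       variable = "heartbeat", value = 1),
            file.path(dir, "l.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = "p1", variable = "age", value = 1),
            file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = "p1", ttd_minutes = 5, era_year = 2020),
            file.path(dir, "o.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "s.csv"), file.path(dir, "l.csv"),
                           file.path(dir, "o.csv"), small_vocab()),
               "row 1.*heartbeat")
})

test_that("patients with an outcome but no longitudinal rows are rejected", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(patient_id = "p1", time_min = -5,
                       variable = "pulse", value = 80),
            file.path(dir, "l.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = c("p1", "p2"), variable = "age",
                       value = c(1, 2)),
            file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = c("p1", "p2"), ttd_minutes = c(5, 6),
                       era_year = 2020),
            file.path(dir, "o.csv"), row.names = FALSE)
  expect_warning(
    co <- read_cohort(file.path(dir, "s.csv"), file.path(dir, "l.csv"),
                      file.path(dir, "o.csv"), small_vocab()),
    "zero longitudinal rows")
  expect_equal(cohort_ids(co), "p1")
})

test_that("vocabulary YAML round trips with kinds and encodings", {
  v <- default_vocabulary()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_equal(v2$longitudinal_names, v$longitudinal_names)
  expect_equal(v2$longitudinal_kinds, v$longitudinal_kinds)
  expect_equal(v2$static_kinds, v$static_kinds)
  expect_equal(v2$encodings$sex, v$encodings$sex)
})

test_that("the default vocabulary has 25 longitudinal and 5 static channels", {
  v <- default_vocabulary()
  expect_length(v$longitudinal_names, 25)
  expect_length(v$static_names, 5)
  expect_setequal(v$static_names, c("age", "bmi", "dialysis", "sex", "weight"))
  expect_false(anyDuplicated(c(v$longitudinal_names, v$static_names)) > 0)
})
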