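test_that("channel summaries follow the top-five/bottom-five transforms", {
  s <- mk_series(seq(-100, -10, by = 10),
                 cbind(1:10, rep(3, 10), rep(5, 10)))
  expect_equal(summarize_channel(s, "pulse", "range"), mean(6:10) - mean(1:5))
  expect_equal(summarize_channel(s, "pulse", "mean"), 5.5)
  expect_equal(summarize_channel(s, "pulse", "min"), mean(1:5))
  expect_equal(summarize_channel(s, "pulse", "max"), mean(6:10))
  # fewer than 5 observations: range falls back to max - min
  s3 <- mk_series(c(-30, -20, -10), cbind(c(1, 2, 3), c(4, 4, 4), c(5, 5, 5)))
  expect_equal(summarize_channel(s3, "pulse", "range"), 2)
  # constant series
  expect_equal(summarize_channel(s3, "spo2", "range"), 0)
  expect_equal(summarize_channel(s3, "spo2", "mean"), 4)
  expect_equal(summarize_channel(s3, "spo2", "min"), 4)
  expect_error(summarize_channel(s3, "nope"), "unknown channel")
})

test_that("summaries use only actually observed values", {
  vals <- cbind(c(10, 9999, 12), c(1, 1, 1), c(5, 5, 5))
  msk <- cbind(c(1, 0, 1), c(1, 1, 1), c(1, 1, 1))  # 9999 is imputed garbage
  s <- mk_series(c(-30, -20, -10), vals, msk)
  expect_equal(summarize_channel(s, "pulse", "max"), mean(c(10, 12)))
  expect_equal(summarize_channel(s, "pulse", "range"), 2)
  # zero observed values -> NA flag
  s0 <- mk_series(-10, cbind(NA, 1, NA), cbind(0, 1, 0))
  expect_true(is.na(summarize_channel(s0, "pulse", "mean")))
})

test_that("the identity permutation yields a delta of exactly zero", {
  sc <- single_scenario()
  n <- length(sc$split$test)
  imp <- permutation_importance(sc$fits[[1]], sc$split$test,
                                variables = c("pulse", "age"),
                                task = 30, .permutations = list(seq_len(n)))
  expect_equal(imp$delta, c(0, 0))
})

test_that("unknown variables are rejected", {
  sc <- single_scenario()
  expect_error(permutation_importance(sc$fits[[1]], sc$split$test,
                                      variables = "flux"), "unknown variable")
})

test_that("the informative channel ranks first; noise channels center at zero", {
  sc <- single_scenario()
  vars <- c("pulse", "spo2", "gcs", "map", "hemoglobin", "lactate",
            "age", "bmi")
  imps <- lapply(seq_along(sc$fits), function(i)
    permutation_importance(sc$fits[[i]], sc$split$test, variables = vars,
                           task = 30, n_repeats = 3, seed = 20 + i))
  delta <- rowMeans(sapply(imps, `[[`, "delta"))
  names(delta) <- vars
  expect_equal(names(which.max(delta)), "pulse")
  # channels the generative model ignores have |mean delta| within noise
  for (v in c("hemoglobin", "lactate", "bmi")) {
    sds <- sapply(imps, function(im) im$sd[im$variable == v])
    expect_lt(abs(delta[v]), 2 * max(mean(sds), 0.01))
  }
})

test_that("phenotypes are deterministic and sized by the config", {
  sc <- single_scenario()
  ph <- extract_phenotypes(sc$fits[[1]], sc$split$test)
  expect_equal(dim(ph), c(length(sc$split$test),
                          sc$fits[[1]]$config$phenotype_dim))
  expect_identical(ph, extract_phenotypes(sc$fits[[1]], sc$split$test))
  # identical patients map to identical phenotypes
  co <- sc$split$test[1:3]
  twin <- co$records[[1]]; twin$patient_id <- "twin"
  co2 <- ttd_cohort(c(co$records, list(twin)), co$vocabulary)
  ph2 <- extract_phenotypes(sc$fits[[1]], co2)
  expect_equal(unname(ph2["twin", ]), unname(ph2[1, ]))
  # phenotypes differ when the label-relevant channel differs
  expect_gt(max(dist(ph)), 0)
})

test_that("2-D embeddings preserve obvious cluster structure", {
  skip_if_not_installed("cluster")
  set.seed(9)
  blobs <- rbind(matrix(rnorm(40 * 5, 0), 40, 5),
                 matrix(rnorm(40 * 5, 6), 40, 5))
  grp <- rep(1:2, each = 40)
  for (method in c("nmds", "pca")) {
    xy <- embed_2d(blobs, method = method, seed = 1)
    expect_equal(dim(xy), c(80, 2))
    sil <- cluster::silhouette(grp, dist(xy))
    expect_gt(mean(sil[, 3]), 0.5)
  }
  expect_identical(embed_2d(blobs, seed = 1), embed_2d(blobs, seed = 1))
  expect_error(embed_2d(blobs[1:5, ]), "at least 10")
})

test_that("clustering separates a planted shift and is null on identical groups", {
  set.seed(10)
  n <- 60
  recs <- lapply(seq_len(n), function(i) {
    base <- if (i <= n / 2) 60 else 110   # pulse level differs by cluster
    mk_record(paste0("p", i), c(-60, -40, -20, -10, -5),
              cbind(rnorm(5, base, 3), rnorm(5, 95, 1), round(runif(5, 3, 8))),
              ttd = rlnorm(1, 2, 1), year = 2018)
  })
  co <- ttd_cohort(recs, small_vocab())
  # planted 2-cluster phenotypes with the first coordinate shifted
  ph <- cbind(c(rnorm(n / 2, -3, 0.4), rnorm(n / 2, 3, 0.4)),
              matrix(rnorm(n * 2, 0, 0.4), n, 2))
  cc <- cluster_and_compare(ph, co, variables = c("pulse:mean", "ttd_log"),
                            n_clusters = 2, seed = 1)
  p_pulse <- cc$tests$p_value[cc$tests$variable == "pulse:mean"]
  expect_lt(p_pulse, 0.01)
  # clusters with identical clinical profiles: nothing separates them
  ph0 <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  recs0 <- lapply(seq_len(n), function(i) {
    r <- recs[[i]]
    r$series$values[, "pulse"] <- 80  # every patient identical on this channel
    r
  })
  cc0 <- cluster_and_compare(ph0, ttd_cohort(recs0, small_vocab()),
                             variables = "pulse:mean", n_clusters = 2, seed = 2)
  expect_equal(cc0$tests$p_value, 1)
  # the TTD zoom filter restricts the clustered subset
  ccz <- cluster_and_compare(ph, co, variables = "ttd_log", n_clusters = 2,
                             seed = 1, max_ttd = 120)
  expect_equal(length(ccz$cluster), sum(cohort_ttd(co) < 120))
})

test_that("phenoscape views assemble coordinates, clusters and colorings", {
  sc <- single_scenario()
  sub <- sc$split$test[1:60]
  view <- phenoscape_view(sc$fits[[1]], sub, method = "pca",
                          variables = c("ttd_log", "pulse:range", "bmi"),
                          n_clusters = 3, seed = 1)
  expect_equal(nrow(view), 60)
  expect_true(all(c("patient_id", "dim1", "dim2", "cluster", "label",
                    "ttd_log", "pulse:range", "bmi") %in% names(view)))
  expect_true(all(is.finite(view$dim1)))
  cc <- attr(view, "clusters")
  expect_s3_class(cc, "ttd_phenoscape")
  expect_equal(ncol(cc$means), 3)
})
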