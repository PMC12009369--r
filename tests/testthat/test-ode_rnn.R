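test_that("analytic gradients match finite differences for every cell type", {
  cases <- list(list("gru", TRUE, "euler"), list("gru", TRUE, "rk4"),
                list("gru", FALSE, "euler"), list("lstm", FALSE, "euler"),
                list("rnn", FALSE, "euler"))
  for (cs in cases) {
    mdl <- tiny_model(cell = cs[[1]], use_ode = cs[[2]], solver = cs[[3]],
                      seed = 42)
    mdl$core_cfg$class_weights <- c(1, 1.5, 0.7, 1)
    pats <- rand_patients(3, seed = 11)
    theta <- ttdcast:::flatten_params(mdl$params)
    fval <- function(th) {
      ttdcast:::.ttd_core_batch(ttdcast:::unflatten_params(th, mdl$shapes),
                                pats, mdl$core_cfg, FALSE, FALSE)$loss
    }
    res <- core_run(mdl, pats, want_grad = TRUE)
    ga <- ttdcast:::flatten_params(res$grads[names(mdl$shapes)])
    eps <- 1e-4
    set.seed(2)
    idx <- sort(sample(length(theta), 60))
    gn <- vapply(idx, function(j) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      (fval(tp) - fval(tm)) / (2 * eps)
    }, 0)
    rel <- abs(ga[idx] - gn) / pmax(abs(gn) + abs(ga[idx]), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("compiled forward pass agrees with the R reference implementation", {
  for (solver in c("euler", "rk4")) {
    mdl <- tiny_model(cell = "gru", use_ode = TRUE, solver = solver, seed = 9)
    pats <- rand_patients(5, seed = 3)
    res <- core_run(mdl, pats, want_latent = TRUE)
    for (i in seq_along(pats)) {
      ref <- ref_forward(mdl$params, pats[[i]], use_ode = TRUE,
                         solver = solver, max_step_h = 0.5)
      expect_equal(as.numeric(res$probs[i, ]), ref$p, tolerance = 1e-10)
      expect_equal(as.numeric(res$phenotypes[i, ]), ref$z, tolerance = 1e-10)
    }
  }
})

test_that("ode_evolve: zero field is the identity, euler matches its definition", {
  h <- c(1, -2, 0.5)
  expect_equal(ode_evolve(h, 0, 5, function(h) rep(0, 3)), h)
  expect_equal(ode_evolve(h, 2, 2, function(h) h), h)  # empty interval
  A <- matrix(c(-0.5, 0.2, 0, -0.3, 0.1, 0.4, 0, 0, -0.2), 3, 3)
  f <- function(h) as.numeric(A %*% h)
  # one explicit euler step over the whole interval
  expect_equal(ode_evolve(h, 0, 0.7, f, solver = "euler", max_step = 0.7),
               h + 0.7 * f(h))
})

test_that("rk4 agrees with the matrix-exponential solution and tiny-step euler", {
  skip_if_not_installed("Matrix")
  A <- matrix(c(-0.5, 0.2, 0, -0.3, 0.1, 0.4, 0, 0, -0.2), 3, 3)
  f <- function(h) as.numeric(A %*% h)
  h <- c(1, -2, 0.5); dt <- 2
  exact <- as.numeric(Matrix::expm(A * dt) %*% h)
  rk <- ode_evolve(h, 0, dt, f, solver = "rk4", max_step = 0.25)
  eu_tiny <- ode_evolve(h, 0, dt, f, solver = "euler", max_step = 0.002)
  expect_equal(rk, exact, tolerance = 1e-6)
  expect_equal(rk, eu_tiny, tolerance = 1e-4)
})

test_that("solver error shrinks at the expected order when halving the step", {
  skip_if_not_installed("Matrix")
  A <- matrix(c(-0.5, 0.2, 0, -0.3, 0.1, 0.4, 0, 0, -0.2), 3, 3)
  f <- function(h) as.numeric(A %*% h)
  h <- c(1, -2, 0.5); dt <- 2
  exact <- as.numeric(Matrix::expm(A * dt) %*% h)
  err <- function(solver, step)
    sqrt(sum((ode_evolve(h, 0, dt, f, solver = solver, max_step = step) - exact)^2))
  e1 <- err("euler", 0.5); e2 <- err("euler", 0.25)
  expect_gt(e1 / e2, 1.7)            # ~ first order
  r1 <- err("rk4", 0.5); r2 <- err("rk4", 0.25)
  expect_gt(r1 / r2, 8)              # >= third order on smooth dynamics
})

test_that("gru_update gates behave as forced", {
  k <- 3; H <- 4; D <- 2 * k + 1
  w <- list(Wz = matrix(0, H, D + H), bz = rep(20, H),    # z ~ 1
            Wr = matrix(0, H, D + H), br = rep(0, H),
            Wh = matrix(rnorm(H * (D + H), 0, 0.3), H, D + H), bh = rep(0, H))
  h <- c(0.3, -1, 0.5, 2)
  x <- c(1, 2, 3); m <- c(1, 1, 0)
  expect_equal(gru_update(h, x, m, 0.5, w), h, tolerance = 1e-8)
  # update gate forced to 0 -> candidate state
  w0 <- w; w0$bz <- rep(-20, H)
  cand <- tanh(as.numeric(w$Wh %*% c(x, m, 0.5, (1 / (1 + exp(0))) * h)))
  expect_equal(gru_update(h, x, m, 0.5, w0), cand, tolerance = 1e-8)
  # reproducible under fixed weights and inputs
  expect_identical(gru_update(h, x, m, 0.5, w0), gru_update(h, x, m, 0.5, w0))
  expect_error(gru_update(h, c(1, 2), c(1, 1), 0.5, w), "dimensions")
})

test_that("encoding handles single observations and ignores absolute time", {
  mdl <- tiny_model(seed = 5)
  one <- list(list(X = matrix(c(0.5, -1, 2), 1, 3), M = matrix(1, 1, 3),
                   dt = 0, s = c(0.1, -0.2), y = 1L))
  res <- core_run(mdl, one, want_latent = TRUE)
  expect_true(all(is.finite(res$phenotypes)))
  # shifting all observation times by a constant leaves the encoding
  # unchanged: only the gaps enter the computation
  co <- small_cohort()
  fit <- ttd_fit(co, "ode_rnn", ttd_config(epochs = 1), seed = 1)
  shift_rec <- function(r, by) {
    r$series$times <- r$series$times - by
    r
  }
  co_shift <- ttd_cohort(lapply(co$records, shift_rec, by = 500),
                         co$vocabulary)
  expect_identical(predict(fit, co), predict(fit, co_shift))
})

test_that("zeroed ODE weights reduce the ODE-RNN to the plain GRU exactly", {
  mdl <- tiny_model(cell = "gru", use_ode = TRUE, seed = 10)
  for (nm in c("ode_W1", "ode_b1", "ode_W2", "ode_b2"))
    mdl$params[[nm]][] <- 0
  gru <- tiny_model(cell = "gru", use_ode = FALSE, seed = 10)
  # identical shared weights for the common parameters
  for (nm in names(gru$shapes)) gru$params[[nm]] <- mdl$params[[nm]]
  pats <- rand_patients(20, seed = 77)
  a <- core_run(mdl, pats, want_latent = TRUE)
  b <- core_run(gru, pats, want_latent = TRUE)
  expect_identical(a$probs, b$probs)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("predictions live on the probability simplex", {
  mdl <- tiny_model(seed = 3)
  pats <- rand_patients(10, seed = 4)
  p <- core_run(mdl, pats)$probs
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  # zero classifier output layer -> exactly uniform
  mdl$params$cls_W2[] <- 0; mdl$params$cls_b2[] <- 0
  pu <- core_run(mdl, pats)$probs
  expect_equal(pu, matrix(0.25, 10, 4), ignore_attr = TRUE)
  # argmax invariant to adding a constant to all logits
  mdl2 <- tiny_model(seed = 3)
  p1 <- core_run(mdl2, pats)$probs
  mdl2$params$cls_b2 <- mdl2$params$cls_b2 + 3.7
  p2 <- core_run(mdl2, pats)$probs
  expect_equal(max.col(p1), max.col(p2))
})

test_that("out-of-order observation times are rejected upstream", {
  expect_error(mk_series(c(-5, -30), rbind(c(80, 95, 6), c(81, 94, 6))),
               "strictly increasing")
})

test_that("halving max_step changes the encoding by a shrinking amount", {
  mdl <- tiny_model(cell = "gru", use_ode = TRUE, seed = 12, jitter = 0.3)
  pats <- rand_patients(6, seed = 13, max_len = 5)
  enc <- function(step_h) {
    m <- mdl
    m$core_cfg$max_step_h <- step_h
    core_run(m, pats, want_latent = TRUE)$phenotypes
  }
  ref <- enc(0.002)   # near-converged reference
  d1 <- sqrt(sum((enc(0.8) - ref)^2))
  d2 <- sqrt(sum((enc(0.4) - ref)^2))
  d3 <- sqrt(sum((enc(0.2) - ref)^2))
  expect_gt(d1, d2)
  expect_gt(d2, d3)
})

test_that("a blown-up vector field raises the non-finite state error", {
  mdl <- tiny_model(cell = "gru", use_ode = TRUE, seed = 2)
  # constant near-overflow drift: the state overflows after a few euler steps
  mdl$params$ode_W1[] <- 0; mdl$params$ode_b1[] <- 0
  mdl$params$ode_W2[] <- 0; mdl$params$ode_b2[] <- 1e308
  pat <- list(X = matrix(rnorm(9), 3, 3), M = matrix(1, 3, 3),
              dt = c(0, 2, 2), s = c(0, 0), y = 1L)
  expect_error(core_run(mdl, list(pat)), "non-finite")
})

test_that("training is deterministic and learns a near-separable cohort", {
  sim <- simulate_cohort(sim_config(n_patients = 1000, seed = 5,
                                    preset = "strong"))
  stats <- normalization_stats(sim$cohort)
  prep <- prepare_cohort(sim$cohort, stats)
  cfg <- ttd_config(epochs = 200, val_fraction = 0, lr = 0.003,
                    batch_size = 64)
  fit <- ttd_fit(prep, "ode_rnn", cfg, seed = 1)
  acc_train <- mean(predict(fit, prep, type = "class") == prep$labels)
  expect_gt(acc_train, 0.85)
  # two short runs with the same seed coincide exactly
  cfg2 <- ttd_config(epochs = 3)
  f1 <- ttd_fit(prep, "ode_rnn", cfg2, seed = 4)
  f2 <- ttd_fit(prep, "ode_rnn", cfg2, seed = 4)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params, f2$params)
})

test_that("on a null cohort the model cannot beat the marginal predictor", {
  sim <- simulate_cohort(sim_config(n_patients = 900, seed = 6, preset = "null"))
  sp <- temporal_split(sim$cohort)
  stats <- normalization_stats(sp$train)
  ptr <- prepare_cohort(sp$train, stats)
  pte <- prepare_cohort(sp$test, stats)
  fit <- ttd_fit(ptr, "ode_rnn", ttd_config(epochs = 12), seed = 2)
  acc <- mean(predict(fit, pte, type = "class") == pte$labels)
  marg <- max(tabulate(pte$labels + 1L, 4)) / length(pte)
  se <- sqrt(marg * (1 - marg) / length(pte))
  expect_lt(acc, marg + 2 * se)
})

test_that("ensembles report member spread and survive shared convexity", {
  st <- default_study()
  ens <- default_ensemble()
  expect_length(ens$members, 5)
  m <- evaluate_model(ens, st$test)
  expect_equal(nrow(m$per_member), 5)
  # member metrics within [0, 1] imply the mean is too
  expect_true(all(m$per_member >= 0 & m$per_member <= 1))
  expect_true(all(m$mean >= 0 & m$mean <= 1))
  # identical members -> sd exactly 0
  twin <- structure(list(members = list(ens$members[[1]], ens$members[[1]]),
                         kind = "ode_rnn", n_seeds = 2, base_seed = 0),
                    class = "ttd_ensemble")
  mt <- evaluate_model(twin, st$test)
  expect_equal(unname(mt$sd), rep(0, length(mt$sd)))
})
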