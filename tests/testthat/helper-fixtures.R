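# Shared fixtures: a small 3-channel vocabulary for hand-built cases, random
# model/patient generators for the compiled core, an independent R reference
# forward pass, and lazily cached heavy objects shared across test files.

small_vocab <- function() {
  ttd_vocabulary(
    longitudinal_names = c("pulse", "spo2", "gcs"),
    static_names = c("age", "bmi"),
    longitudinal_kinds = c("continuous", "continuous", "ordinal"),
    static_kinds = c("continuous", "continuous"),
    encodings = list())
}

mk_series <- function(times, values, masks = NULL, vocab = small_vocab()) {
  values <- as.matrix(values)
  colnames(values) <- vocab$longitudinal_names[seq_len(ncol(values))]
  if (is.null(masks)) masks <- 1 - is.na(values) * 1
  masks <- as.matrix(masks)
  colnames(masks) <- colnames(values)
  longitudinal_series(times, values, masks)
}

mk_record <- function(id, times, values, masks = NULL, ttd = 10, year = 2018,
                      static = c(age = 60, bmi = 27), vocab = small_vocab()) {
  patient_record(id, static, mk_series(times, values, masks, vocab), ttd, year)
}

# a hand-built 4-patient cohort over the small vocabulary
small_cohort <- function() {
  ttd_cohort(list(
    mk_record("a", c(-90, -30, -5),
              rbind(c(80, 95, 6), c(NA, 92, NA), c(110, NA, 5)), ttd = 5,
              year = 2018),
    mk_record("b", c(-60, -10),
              rbind(c(70, NA, 7), c(75, 90, NA)), ttd = 40, year = 2019),
    mk_record("c", c(-45), rbind(c(88, 97, 3)), ttd = 90, year = 2022),
    mk_record("d", c(-200, -100, -50, -2),
              rbind(c(60, 99, 8), c(65, NA, NA), c(NA, 85, NA), c(120, 80, 4)),
              ttd = 200, year = 2022)),
    small_vocab(), provenance = "synthetic")
}

# random model + patients talking directly to the compiled core
tiny_model <- function(cell = "gru", use_ode = TRUE, solver = "euler",
                       seed = 42, k = 3, l = 2, jitter = 0.1) {
  cfgm <- ttd_config(hidden_dim = 4, phenotype_dim = 3, ode_width = 3,
                     static_width = 3, long_width = 3, fusion_width = 3,
                     classifier_width = 3, static_dim = 2, long_dim = 2,
                     solver = solver, max_step = 30)
  shapes <- ttdcast:::param_shapes(cfgm, k, l, cell, use_ode)
  set.seed(seed)
  params <- ttdcast:::init_params(shapes, seed)
  if (jitter > 0)
    for (nm in names(params))
      params[[nm]] <- params[[nm]] +
        matrix(rnorm(length(params[[nm]]), 0, jitter), nrow(params[[nm]]))
  list(config = cfgm, shapes = shapes, params = params, k = k, l = l,
       core_cfg = ttdcast:::core_cfg(cfgm, cell, use_ode, rep(1, 4)))
}

rand_patients <- function(n_pat, k = 3, l = 2, seed = 1, max_len = 6) {
  set.seed(seed)
  lapply(seq_len(n_pat), function(i) {
    n <- sample(1:max_len, 1)
    M <- matrix(rbinom(n * k, 1, 0.6), n, k)
    M[cbind(seq_len(n), sample(k, n, replace = TRUE))] <- 1  # no empty rows
    list(X = matrix(rnorm(n * k), n, k), M = M,
         dt = c(0, runif(n - 1, 0, 3)), s = rnorm(l),
         y = sample(0:3, 1))
  })
}

core_run <- function(model, pats, want_grad = FALSE, want_latent = FALSE) {
  ttdcast:::.ttd_core_batch(model$params, pats, model$core_cfg,
                            want_grad, want_latent)
}

# independent R re-implementation of the ODE-RNN forward pass (GRU cell),
# built on the exported single-step operations
ref_forward <- function(params, pat, use_ode = TRUE, solver = "euler",
                        max_step_h = 0.5) {
  mlp <- function(pre, x) {
    a <- tanh(params[[paste0(pre, "_W1")]] %*% x + params[[paste0(pre, "_b1")]])
    as.numeric(params[[paste0(pre, "_W2")]] %*% a + params[[paste0(pre, "_b2")]])
  }
  h <- as.numeric(params$h0)
  for (i in seq_len(nrow(pat$X))) {
    if (use_ode && i > 1 && pat$dt[i] > 0)
      h <- ode_evolve(h, 0, pat$dt[i], params, solver = solver,
                      max_step = max_step_h)
    h <- gru_update(h, pat$X[i, ], pat$M[i, ], pat$dt[i], params)
  }
  z <- mlp("fusion", c(mlp("static", pat$s), mlp("long", h)))
  logit <- mlp("cls", z)
  p <- exp(logit - max(logit))
  list(z = z, p = p / sum(p))
}

# brute-force oracles -----------------------------------------------------

# pair-counting (Mann-Whitney) ROC-AUC
auc_oracle <- function(probs, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
  tot / (length(pos) * length(neg))
}

# direct bin-enumeration ECE
ece_oracle <- function(probs, labels, n_bins = 10) {
  tot <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    sel <- if (b < n_bins) probs >= lo & probs < hi else probs >= lo & probs <= hi
    if (!any(sel)) next
    tot <- tot + sum(sel) / length(probs) *
      abs(mean(probs[sel]) - mean(labels[sel]))
  }
  tot
}

# lazily cached heavy fixtures (shared by acceptance and interpretation tests)
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_study <- function() cached("default_study", function() {
  sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 1))
  sp <- temporal_split(sim$cohort)
  stats <- normalization_stats(sp$train)
  list(sim = sim, split = sp, stats = stats,
       train = prepare_cohort(sp$train, stats),
       test = prepare_cohort(sp$test, stats))
})

default_ensemble <- function() cached("default_ensemble", function() {
  st <- default_study()
  ttd_fit_ensemble(st$train, "ode_rnn", ttd_config(epochs = 30),
                   n_seeds = 5, seed = 100)
})

# scenario where heart rate is the single informative channel, with three
# independently initialized models
single_scenario <- function() cached("single_scenario", function() {
  sim <- simulate_cohort(sim_config(n_patients = 1200, seed = 13,
                                    preset = "single"))
  sp <- temporal_split(sim$cohort)
  stats <- normalization_stats(sp$train)
  fits <- lapply(1:3, function(s)
    ttd_fit(prepare_cohort(sp$train, stats), "ode_rnn",
            ttd_config(epochs = 60, patience = 15), seed = s))
  list(sim = sim, split = sp, stats = stats, fits = fits)
})
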