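#' Fit a TTD classifier
#'
#' The single entry point for every model kind compared in the package:
#'
#' * `"ode_rnn"` - the main model: GRU updates at observations, learned ODE
#'   dynamics for the hidden state between observations.
#' * `"gru"`, `"lstm"`, `"rnn"` - sequence baselines consuming the identical
#'   input encoding (values, mask, time gap) but without the ODE segment.
#' * `"static"` - gradient-boosted trees (or multinomial logistic) on the
#'   last-observation feature vector; cannot see trajectories.
#' * `"criteria"` - an expert checklist score: the count of satisfied
#'   clinical criteria at extubation, thresholded on the training split.
#'
#' All kinds consume the same prepared inputs, so comparisons are not
#' confounded by preprocessing differences.
#'
#' @param x a training [ttd_cohort()] or a [prepare_cohort()] result. When a
#'   cohort is given, normalization statistics are computed from it (it is
#'   the training split; never pass test data here).
#' @param kind model kind, see above.
#' @param config a [ttd_config()].
#' @param stats optional precomputed [normalization_stats()].
#' @param seed RNG seed for initialization and batch order (defaults to
#'   `config$seed`).
#' @param criteria a [criteria_set()] (kind `"criteria"` only).
#' @param engine `"xgboost"` or `"multinom"` (kind `"static"` only).
#' @param horizon_min,normalize forwarded to [prepare_cohort()] when `x` is a
#'   cohort.
#' @return An object of class `ttd_model` with methods [predict.ttd_model()],
#'   `print()`, `summary()`, `coef()`, `plot()` (training curve) and
#'   `simulate()` (label draws from the predictive distribution).
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_patients = 120, seed = 7))
#' sp <- temporal_split(sim$cohort)
#' fit <- ttd_fit(sp$train, "ode_rnn", ttd_config(epochs = 3))
#' head(predict(fit, sp$test))
#' }
#' @export
ttd_fit <- function(x, kind = c("ode_rnn", "gru", "lstm", "rnn", "static", "criteria"),
                    config = ttd_config(), stats = NULL, seed = config$seed,
                    criteria = default_criteria(), engine = "xgboost",
                    horizon_min = NULL, normalize = TRUE) {
  kind <- match.arg(kind)
  if (inherits(x, "ttd_cohort")) {
    if (is.null(stats)) stats <- normalization_stats(x)
    prepared <- prepare_cohort(x, stats, bin_edges = config$bin_edges,
                               normalize = normalize, horizon_min = horizon_min,
                               gap_cap_min = config$gap_cap)
    raw_cohort <- x
  } else if (inherits(x, "ttd_prepared")) {
    prepared <- x
    stats <- prepared$stats
    raw_cohort <- NULL
  } else stop("x must be a ttd_cohort or a ttd_prepared object")

  fit <- switch(kind,
    static = fit_static_model(prepared, config, seed = seed, engine = engine),
    criteria = fit_criteria_model(prepared, config, criteria = criteria,
                                  raw_cohort = raw_cohort, stats = stats),
    fit_sequence_model(prepared, kind, config, seed = seed))
  fit$stats <- stats
  fit$vocabulary <- prepared$vocabulary
  fit$bin_edges <- config$bin_edges
  fit$normalize <- prepared$normalize
  fit$gap_cap <- prepared$gap_cap_min
  fit$n_train <- length(prepared)
  class(fit) <- c(paste0("ttd_", kind), "ttd_model")
  fit
}

# ---- sequence models (ODE-RNN and recurrent baselines) ----------------------

kind_to_cell <- function(kind) switch(kind, ode_rnn = "gru", kind)

fit_sequence_model <- function(prepared, kind, config, seed) {
  cell <- kind_to_cell(kind)
  use_ode <- kind == "ode_rnn"
  k <- vocab_k(prepared$vocabulary)
  l <- vocab_l(prepared$vocabulary)
  n <- length(prepared)
  C <- config$n_classes

  cwts <- rep(1, C)
  if (identical(config$class_weights, "inverse")) {
    cnt <- tabulate(prepared$labels + 1L, nbins = C)
    cwts <- n / (C * pmax(cnt, 1))
  }
  cfg <- core_cfg(config, cell, use_ode, cwts)
  pats <- core_patients(prepared, config)

  set.seed(seed)
  n_val <- if (config$val_fraction > 0 && n >= 20)
    max(2L, floor(config$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer()
  tr_idx <- setdiff(seq_len(n), val_idx)

  shapes <- param_shapes(config, k, l, cell, use_ode)
  theta <- flatten_params(init_params(shapes, seed))
  if (config$h0 == "zeros") { }  # init is zero either way; "learned" lets it move
  np <- length(theta)
  m <- v <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
  h0_idx <- seq_len(prod(shapes$h0))   # frozen when h0 = "zeros"

  best_val <- Inf; best_theta <- theta; best_epoch <- 0L; bad <- 0L
  loss_trace <- val_trace <- numeric(0)

  for (ep in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    ep_loss <- 0; ep_w <- 0
    for (start in seq(1, length(perm), by = config$batch_size)) {
      bidx <- perm[start:min(start + config$batch_size - 1, length(perm))]
      res <- .ttd_core_batch(unflatten_params(theta, shapes), pats[bidx],
                             cfg, TRUE, FALSE)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss); reduce lr or max_step")
      grad <- flatten_params(res$grads[names(shapes)]) / res$wsum
      if (config$h0 == "zeros") grad[h0_idx] <- 0
      tstep <- tstep + 1
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mh <- m / (1 - b1^tstep); vh <- v / (1 - b2^tstep)
      theta <- theta - config$lr * mh / (sqrt(vh) + eps)
      ep_loss <- ep_loss + res$loss; ep_w <- ep_w + res$wsum
    }
    loss_trace <- c(loss_trace, ep_loss / ep_w)
    if (n_val > 0) {
      vres <- .ttd_core_batch(unflatten_params(theta, shapes), pats[val_idx],
                              cfg, FALSE, FALSE)
      vl <- vres$loss / vres$wsum
      val_trace <- c(val_trace, vl)
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_theta <- theta; best_epoch <- ep; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    } else {
      best_theta <- theta; best_epoch <- ep
    }
  }
  list(kind = kind, cell = cell, use_ode = use_ode,
       params = unflatten_params(best_theta, shapes), shapes = shapes,
       config = config, class_weights = cwts, seed = seed,
       loss_trace = loss_trace, val_trace = val_trace,
       best_epoch = best_epoch)
}

# run the compiled core on a prepared cohort with a model's weights
seq_forward <- function(object, prepared, want_latent = FALSE) {
  cfg <- core_cfg(object$config, object$cell, object$use_ode,
                  object$class_weights)
  pats <- core_patients(prepared, object$config)
  .ttd_core_batch(object$params, pats, cfg, FALSE, want_latent)
}

# prepare newdata consistently with how the model was trained
prepare_newdata <- function(object, newdata) {
  if (inherits(newdata, "ttd_prepared")) return(newdata)
  stopifnot(inherits(newdata, "ttd_cohort"))
  prepare_cohort(newdata, object$stats, bin_edges = object$bin_edges,
                 normalize = object$normalize, gap_cap_min = object$gap_cap)
}

#' Predict TTD-category probabilities
#'
#' @param object a fitted [ttd_fit()] model.
#' @param newdata a [ttd_cohort()] or [prepare_cohort()] result.
#' @param type `"prob"` for the n x 4 probability matrix (rows sum to 1),
#'   `"class"` for argmax categories (ties broken toward the lower, more
#'   conservative category), or `"phenotype"` for the latent-phenotype matrix
#'   (sequence models only).
#' @param ... unused.
#' @export
predict.ttd_model <- function(object, newdata, type = c("prob", "class", "phenotype"),
                              ...) {
  type <- match.arg(type)
  prepared <- prepare_newdata(object, newdata)
  if (object$kind %in% c("static", "criteria")) {
    if (type == "phenotype")
      stop("latent phenotypes exist only for sequence models")
    pr <- predict_tabular(object, prepared)
  } else {
    res <- seq_forward(object, prepared, want_latent = (type == "phenotype"))
    if (type == "phenotype") {
      ph <- res$phenotypes
      rownames(ph) <- prepared$ids
      return(ph)
    }
    pr <- res$probs
  }
  rownames(pr) <- prepared$ids
  colnames(pr) <- paste0("p", seq_len(ncol(pr)) - 1L)
  if (type == "class") return(max.col(pr, ties.method = "first") - 1L)
  pr
}

#' Latent phenotype of patients under a fitted sequence model
#'
#' @param model a fitted sequence [ttd_fit()] model (or ensemble, in which
#'   case the first member is used).
#' @param cohort a [ttd_cohort()] or prepared cohort.
#' @return Numeric matrix, one row per patient, `phenotype_dim` columns.
#' @export
extract_phenotypes <- function(model, cohort) {
  if (inherits(model, "ttd_ensemble")) model <- model$members[[1]]
  predict(model, cohort, type = "phenotype")
}

#' @export
print.ttd_model <- function(x, ...) {
  cat("TTD classifier, kind:", x$kind, "\n")
  cat("  trained on", x$n_train, "patients;",
      length(x$bin_edges) + 1, "categories (edges",
      paste(x$bin_edges, collapse = "/"), "min)\n")
  if (!is.null(x$loss_trace) && length(x$loss_trace))
    cat(sprintf("  %d epochs run, best epoch %d, final train loss %.4f\n",
                length(x$loss_trace), x$best_epoch, tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.ttd_model <- function(object, ...) {
  out <- list(kind = object$kind, n_train = object$n_train,
              n_parameters = if (!is.null(object$params))
                length(flatten_params(object$params)) else NA_integer_,
              best_epoch = object$best_epoch,
              loss_trace = object$loss_trace, val_trace = object$val_trace)
  class(out) <- "summary.ttd_model"
  out
}

#' @export
print.summary.ttd_model <- function(x, ...) {
  cat("TTD classifier summary\n  kind:", x$kind,
      "\n  training patients:", x$n_train,
      "\n  parameters:", x$n_parameters, "\n")
  if (length(x$loss_trace)) {
    cat("  train loss:", sprintf("%.4f", head(x$loss_trace, 1)), "->",
        sprintf("%.4f", tail(x$loss_trace, 1)),
        "over", length(x$loss_trace), "epochs\n")
    if (length(x$val_trace))
      cat("  best validation loss:", sprintf("%.4f", min(x$val_trace)),
          "at epoch", x$best_epoch, "\n")
  }
  invisible(x)
}

#' @export
coef.ttd_model <- function(object, ...) {
  if (is.null(object$params)) return(NULL)
  th <- flatten_params(object$params)
  names(th) <- rep(names(object$shapes),
                   vapply(object$shapes, prod, 0))
  th
}

#' @export
plot.ttd_model <- function(x, ...) {
  if (is.null(x$loss_trace) || !length(x$loss_trace)) {
    warning("no training trace to plot"); return(invisible(x))
  }
  ep <- seq_along(x$loss_trace)
  ylim <- range(c(x$loss_trace, x$val_trace))
  graphics::plot(ep, x$loss_trace, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", ylim = ylim,
                 main = paste("training curve -", x$kind), ...)
  if (length(x$val_trace)) {
    graphics::lines(seq_along(x$val_trace), x$val_trace, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' @export
simulate.ttd_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, type = "prob")
  out <- vapply(seq_len(nsim), function(i)
    apply(pr, 1, function(p) sample.int(length(p), 1, prob = p) - 1L),
    integer(nrow(pr)))
  out <- matrix(out, nrow = nrow(pr), dimnames = list(rownames(pr), NULL))
  out
}

# ---- ensembles ---------------------------------------------------------------

#' Train an ensemble of models with different initializations
#'
#' Fits `n_seeds` models with seeds `seed + 0 .. seed + n_seeds - 1`.
#' Downstream, [evaluate_model()] reports each metric as mean +/- sd across
#' members. A member whose training diverges is dropped with a warning; at
#' least two survivors are required.
#'
#' @inheritParams ttd_fit
#' @param n_seeds number of members (>= 2).
#' @return An object of class `ttd_ensemble`.
#' @export
ttd_fit_ensemble <- function(x, kind = "ode_rnn", config = ttd_config(),
                             n_seeds = 5, seed = config$seed, ...) {
  stopifnot(n_seeds >= 2)
  members <- list()
  for (i in seq_len(n_seeds) - 1L) {
    fit <- tryCatch(ttd_fit(x, kind = kind, config = config, seed = seed + i, ...),
                    error = function(e) {
                      warning("ensemble member with seed ", seed + i,
                              " failed: ", conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit)) members[[length(members) + 1L]] <- fit
  }
  if (length(members) < 2)
    stop("fewer than 2 ensemble members survived training")
  structure(list(members = members, kind = kind, n_seeds = n_seeds,
                 base_seed = seed),
            class = "ttd_ensemble")
}

#' @export
print.ttd_ensemble <- function(x, ...) {
  cat("TTD model ensemble:", length(x$members), "members of kind", x$kind,
      "(base seed", paste0(x$base_seed, ")"), "\n")
  invisible(x)
}

#' @export
predict.ttd_ensemble <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  member_probs <- lapply(object$members, predict, newdata = newdata, type = "prob")
  pr <- Reduce(`+`, member_probs) / length(member_probs)
  if (type == "class") return(max.col(pr, ties.method = "first") - 1L)
  attr(pr, "member_probs") <- member_probs
  pr
}

# ---- low-level operations (exposed for inspection and testing) ---------------

#' Evolve a hidden state through the learned (or supplied) ODE
#'
#' Numerically integrates `dh/dt = f(h)` over `[t_from, t_to]` with a
#' fixed-step solver, using steps no longer than `max_step` (same time unit
#' as `t_from`/`t_to`). With `t_to == t_from` this is the identity.
#'
#' @param h numeric hidden-state vector.
#' @param t_from,t_to interval endpoints, `t_to >= t_from`.
#' @param f derivative: either a function `h -> dh/dt` or a parameter list
#'   with elements `ode_W1`, `ode_b1`, `ode_W2`, `ode_b2` (the model's MLP
#'   vector field).
#' @param solver `"euler"` or `"rk4"`.
#' @param max_step maximum step size, > 0.
#' @export
ode_evolve <- function(h, t_from, t_to, f, solver = c("euler", "rk4"),
                       max_step = 15) {
  solver <- match.arg(solver)
  stopifnot(t_to >= t_from, max_step > 0)
  if (is.list(f)) {
    W1 <- f$ode_W1; b1 <- as.numeric(f$ode_b1)
    W2 <- f$ode_W2; b2 <- as.numeric(f$ode_b2)
    f <- function(h) as.numeric(W2 %*% tanh(W1 %*% h + b1) + b2)
  }
  dt <- t_to - t_from
  if (dt == 0) return(h)
  ns <- ceiling(dt / max_step)
  delta <- dt / ns
  for (i in seq_len(ns)) {
    if (solver == "euler") {
      h <- h + delta * f(h)
    } else {
      k1 <- f(h)
      k2 <- f(h + delta / 2 * k1)
      k3 <- f(h + delta / 2 * k2)
      k4 <- f(h + delta * k3)
      h <- h + delta / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(h)))
      stop("non-finite state during integration; try a smaller max_step")
  }
  h
}

#' One GRU update at an observation
#'
#' Standard GRU cell arithmetic on the concatenated input
#' `[x; m; delta_t]`: reset and update gates, candidate state, convex
#' combination. With the update gate saturated at 1 the state is unchanged;
#' at 0 the state equals the candidate.
#'
#' @param h hidden state.
#' @param x observed (filled) channel values.
#' @param m 0/1 observation mask.
#' @param delta_t time-gap feature (hours).
#' @param weights list with `Wz`, `bz`, `Wr`, `br`, `Wh`, `bh`.
#' @export
gru_update <- function(h, x, m, delta_t, weights) {
  u <- c(x, m, delta_t)
  if (ncol(weights$Wz) != length(u) + length(h))
    stop("weight dimensions do not match input (expected input width ",
         ncol(weights$Wz) - length(h), ", got ", length(u), ")")
  sig <- function(a) 1 / (1 + exp(-a))
  cat1 <- c(u, h)
  z <- sig(as.numeric(weights$Wz %*% cat1 + weights$bz))
  r <- sig(as.numeric(weights$Wr %*% cat1 + weights$br))
  g <- tanh(as.numeric(weights$Wh %*% c(u, r * h) + weights$bh))
  z * h + (1 - z) * g
}

#' Encode one prepared patient into the latent phenotype
#'
#' Runs the full ODE-RNN recursion (initial state, ODE evolution between
#' observations, GRU updates at observations) and the static/longitudinal
#' fusion head for a single patient.
#'
#' @param object a fitted sequence [ttd_fit()] model.
#' @param prepared a `ttd_prepared` cohort (all patients are encoded).
#' @return Matrix of latent phenotypes, one row per patient.
#' @export
encode <- function(object, prepared) {
  stopifnot(inherits(object, "ttd_model"), !is.null(object$params))
  res <- seq_forward(object, prepared, want_latent = TRUE)
  ph <- res$phenotypes
  rownames(ph) <- prepared$ids
  ph
}
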