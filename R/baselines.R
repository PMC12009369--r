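## Comparator models: last-observation features, the clinical-criteria score,
## and the static ML baseline. Sequence baselines (rnn/lstm/gru) share the
## training code in fit.R.

#' Last-observation feature vector
#'
#' Static methods cannot see trajectories; they are trained on the last
#' available observation of each channel at the time of extubation (the
#' imputed value if a channel was never observed), concatenated with the
#' static variables. With the default vocabulary the feature vector has
#' length k + l = 30.
#'
#' @param prepared a [prepare_cohort()] result.
#' @param raw if `TRUE`, undo the z-scoring so features are in raw clinical
#'   units (needed to evaluate criteria thresholds such as "heart rate < 30").
#' @return Numeric matrix, one row per patient, named columns.
#' @export
last_observation_features <- function(prepared, raw = FALSE) {
  stopifnot(inherits(prepared, "ttd_prepared"))
  vocab <- prepared$vocabulary
  k <- vocab_k(vocab); l <- vocab_l(vocab)
  feat <- t(vapply(prepared$patients, function(p) {
    # after forward-fill the final row holds each channel's latest observed
    # value (training mean where never observed)
    c(p$X[nrow(p$X), ], p$s)
  }, numeric(k + l)))
  rownames(feat) <- prepared$ids
  colnames(feat) <- c(vocab$longitudinal_names, vocab$static_names)
  if (raw && prepared$normalize) {
    st <- prepared$stats
    for (j in seq_len(k))
      if (st$channel$kind[j] != "binary")
        feat[, j] <- feat[, j] * st$channel$sd[j] + st$channel$mean[j]
    for (j in seq_len(l))
      if (st$static$kind[j] != "binary")
        feat[, k + j] <- feat[, k + j] * st$static$sd[j] + st$static$mean[j]
  }
  feat
}

#' Clinical criteria set
#'
#' A list of threshold criteria, each evaluated on the last available
#' observation of its channel; the score of a patient is the number of
#' satisfied criteria. Mirrors checklist-style DCD candidacy scores.
#'
#' @param criteria data frame with columns `channel`, `comparator` (one of
#'   `<`, `>`, `<=`, `>=`) and `threshold`.
#' @return An object of class `ttd_criteria_set`.
#' @export
criteria_set <- function(criteria) {
  stopifnot(is.data.frame(criteria),
            all(c("channel", "comparator", "threshold") %in% names(criteria)))
  if (!all(criteria$comparator %in% c("<", ">", "<=", ">=")))
    stop("comparator must be one of <, >, <=, >=")
  if (any(!is.finite(criteria$threshold)))
    stop("criteria thresholds must be finite")
  structure(criteria, class = c("ttd_criteria_set", "data.frame"))
}

#' Default (illustrative) criteria set
#'
#' Ships the two canonical printed examples (heart rate < 30, FiO2 > 0.5)
#' plus six plausible placeholder criteria. This is *not* the official
#' 14-item UNOS checklist, which is not public in full; supply your own
#' [criteria_set()] to reproduce a specific score.
#' @export
default_criteria <- function() {
  criteria_set(data.frame(
    channel = c("pulse", "fio2", "spo2", "map", "norepinephrine",
                "peep", "gcs", "ph"),
    comparator = c("<", ">", "<", "<", ">", ">", "<=", "<"),
    threshold = c(30, 0.5, 80, 45, 0.2, 10, 4, 7.2),
    stringsAsFactors = FALSE))
}

#' Criteria score of patients
#'
#' @param features matrix (or single named vector) of raw-unit
#'   last-observation features, as from
#'   `last_observation_features(prepared, raw = TRUE)`.
#' @param criteria a [criteria_set()].
#' @return Integer score(s): the number of satisfied criteria.
#' @export
criteria_score <- function(features, criteria) {
  if (is.null(dim(features))) features <- matrix(features, 1,
                                                 dimnames = list(NULL, names(features)))
  unknown <- setdiff(criteria$channel, colnames(features))
  if (length(unknown))
    stop("criteria refer to unknown channel(s): ", paste(unknown, collapse = ", "))
  score <- integer(nrow(features))
  for (i in seq_len(nrow(criteria))) {
    v <- features[, criteria$channel[i]]
    hit <- switch(criteria$comparator[i],
                  "<"  = v <  criteria$threshold[i],
                  ">"  = v >  criteria$threshold[i],
                  "<=" = v <= criteria$threshold[i],
                  ">=" = v >= criteria$threshold[i])
    score <- score + as.integer(hit)
  }
  score
}

# ---- static ML baseline ------------------------------------------------------

fit_static_model <- function(prepared, config, seed, engine = "xgboost") {
  feat <- last_observation_features(prepared)
  y <- prepared$labels
  C <- config$n_classes
  if (engine == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(feat, label = y)
    set.seed(seed)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = C,
                    max_depth = 4, eta = 0.1, subsample = 1,
                    colsample_bytree = 1, nthread = 1, seed = seed),
      data = dtrain, nrounds = 150, verbose = 0)
    model <- booster
  } else if (engine == "multinom") {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("engine 'multinom' needs the nnet package")
    df <- data.frame(y = factor(y, levels = 0:(C - 1)), feat)
    model <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
  } else stop("unknown static engine: ", engine)
  list(kind = "static", engine = engine, model = model, config = config,
       classes = 0:(C - 1), seed = seed)
}

# ---- criteria baseline -------------------------------------------------------

fit_criteria_model <- function(prepared, config, criteria, raw_cohort = NULL,
                               stats = NULL) {
  stopifnot(inherits(criteria, "ttd_criteria_set"))
  unknown <- setdiff(criteria$channel,
                     c(prepared$vocabulary$longitudinal_names,
                       prepared$vocabulary$static_names))
  if (length(unknown))
    stop("criteria refer to channel(s) outside the vocabulary: ",
         paste(unknown, collapse = ", "))
  feat <- last_observation_features(prepared, raw = TRUE)
  score <- criteria_score(feat, criteria)
  y <- prepared$labels
  C <- config$n_classes
  smax <- nrow(criteria)

  # smoothed per-score class distribution -> pseudo-probabilities; a higher
  # score (sicker patient) should map to shorter-TTD categories
  dist <- matrix(1, smax + 1, C)  # Laplace smoothing
  for (s in 0:smax) {
    sel <- score == s
    if (any(sel)) dist[s + 1, ] <- dist[s + 1, ] + tabulate(y[sel] + 1L, C)
  }
  dist <- dist / rowSums(dist)

  # per-binary-task decision threshold on the integer score, chosen on the
  # training split by maximizing F1
  thresholds <- vapply(seq_along(config$bin_edges), function(ti) {
    pos <- as.integer(y < ti)
    f1s <- vapply(0:(smax + 1), function(t0) {
      pred <- as.integer(score >= t0)
      tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
      if (tp == 0) return(0)
      2 * tp / (2 * tp + fp + fn)
    }, 0)
    (0:(smax + 1))[which.max(f1s)]
  }, 0)
  names(thresholds) <- paste0("lt", config$bin_edges)

  list(kind = "criteria", criteria = criteria, score_dist = dist,
       thresholds = thresholds, config = config, smax = smax)
}

# probability predictions for the tabular kinds
predict_tabular <- function(object, prepared) {
  C <- object$config$n_classes
  if (object$kind == "static") {
    feat <- last_observation_features(prepared)
    if (object$engine == "xgboost") {
      p <- predict(object$model, xgboost::xgb.DMatrix(feat))
      # xgboost >= 3 returns an n x C matrix, older versions a flat vector
      pr <- if (is.matrix(p)) p else matrix(p, ncol = C, byrow = TRUE)
    } else {
      pr <- predict(object$model, newdata = data.frame(feat), type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-class edge
    }
    pr
  } else {  # criteria
    feat <- last_observation_features(prepared, raw = TRUE)
    score <- criteria_score(feat, object$criteria)
    pr <- object$score_dist[pmin(score, object$smax) + 1L, , drop = FALSE]
    attr(pr, "score") <- score
    pr
  }
}
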