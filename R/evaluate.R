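## Metric suite: 4-way accuracy, grouped binary tasks, ROC-AUC, PR-AUC, F1,
## PPV/NPV, expected calibration error, calibration curves, and multi-seed
## mean +/- sd reporting.

#' Grouped binary probability
#'
#' Collapses the 4-way predictive distribution into the probability that TTD
#' is below a threshold, by summing the probabilities of the categories that
#' lie entirely below it (e.g. `< 60` sums categories 0 and 1). The
#' threshold must be one of the label bin edges.
#'
#' @param p probability vector (one patient) or matrix (patients x classes).
#' @param threshold_min grouping threshold in minutes.
#' @param bin_edges the label bin edges.
#' @return Probability of the positive class (TTD < threshold).
#' @examples
#' group_probability(c(0.7, 0.1, 0.1, 0.1), 60)  # 0.8
#' @export
group_probability <- function(p, threshold_min, bin_edges = c(30, 60, 120)) {
  idx <- match(threshold_min, bin_edges)
  if (is.na(idx))
    stop("threshold ", threshold_min, " is not one of the bin edges (",
         paste(bin_edges, collapse = ", "), ")")
  if (is.null(dim(p))) sum(p[seq_len(idx)]) else rowSums(p[, seq_len(idx), drop = FALSE])
}

# trapezoidal/rank ROC-AUC; ties contribute 1/2
roc_auc_score <- function(probs, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# trapezoidal PR-AUC over the grouped-threshold precision/recall points,
# anchored at recall 0 with the precision of the top-scoring group
pr_auc_score <- function(probs, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  o <- order(probs, decreasing = TRUE)
  lab <- labels[o]; pr <- probs[o]
  grp_last <- !duplicated(rev(pr))  # last index of each tied group, reversed
  cum_tp <- cumsum(lab); cum_fp <- cumsum(1 - lab)
  keep <- rev(grp_last)
  tp <- cum_tp[keep]; fp <- cum_fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  r <- c(0, recall); p <- c(precision[1], precision)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Binary classification metrics
#'
#' Standard definitions on hard decisions at `decision_threshold`, plus
#' ROC-AUC (trapezoidal rank statistic; ties count 1/2) and trapezoidal
#' PR-AUC on the predicted probabilities. Degenerate cases follow the
#' convention of reporting 0 with a warning: a predictor that never calls a
#' class has undefined precision for it, reported as 0.
#'
#' @param probs predicted positive-class probabilities in `[0, 1]`.
#' @param labels 0/1 vector of the same length.
#' @param decision_threshold probability cut for hard decisions.
#' @param decisions optional explicit 0/1 decisions (overrides the threshold;
#'   used for integer-score models).
#' @return Named numeric vector: `accuracy`, `f1`, `ppv`, `npv`, `roc_auc`,
#'   `pr_auc`. AUCs are `NA` (with a warning) when only one class is present.
#' @export
binary_metrics <- function(probs, labels, decision_threshold = 0.5,
                           decisions = NULL) {
  if (length(probs) != length(labels)) stop("probs and labels differ in length")
  labels <- as.integer(labels)
  pred <- if (is.null(decisions)) as.integer(probs >= decision_threshold)
          else as.integer(decisions)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / length(labels)
  if (tp + fp == 0) {
    warning("no predicted positives; PPV reported as 0", call. = FALSE)
    ppv <- 0
  } else ppv <- tp / (tp + fp)
  if (tn + fn == 0) {
    warning("no predicted negatives; NPV reported as 0", call. = FALSE)
    npv <- 0
  } else npv <- tn / (tn + fn)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  if (length(unique(labels)) < 2) {
    warning("single-class labels; AUCs undefined (NA)", call. = FALSE)
    roc <- prc <- NA_real_
  } else {
    roc <- roc_auc_score(probs, labels)
    prc <- pr_auc_score(probs, labels)
  }
  c(accuracy = acc, f1 = f1, ppv = ppv, npv = npv, roc_auc = roc, pr_auc = prc)
}

#' Expected calibration error
#'
#' Predicted probabilities are binned into `n_bins` equal-width bins on
#' `[0, 1]`; the ECE is the observation-weighted mean absolute gap between
#' each bin's mean confidence and its empirical positive frequency. Empty
#' bins are skipped.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins number of equal-width bins.
#' @return ECE in `[0, 1]`.
#' @export
ece <- function(probs, labels, n_bins = 10) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  tab <- calibration_curve(probs, labels, n_bins)
  sum(tab$count / length(probs) *
        abs(tab$mean_confidence - tab$empirical_frequency))
}

#' Calibration (reliability) curve data
#'
#' The table behind a reliability diagram: per non-empty probability bin,
#' the mean predicted probability, the empirical positive frequency, and the
#' count. Recomputing the ECE from this table reproduces [ece()] exactly.
#'
#' @inheritParams ece
#' @return Data frame with columns `bin`, `lower`, `upper`,
#'   `mean_confidence`, `empirical_frequency`, `count`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  stopifnot(length(probs) == length(labels))
  labels <- as.numeric(labels)
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)  # 1.0 joins the last bin
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, lower = (b - 1) / n_bins, upper = b / n_bins,
               mean_confidence = mean(probs[sel]),
               empirical_frequency = mean(labels[sel]),
               count = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

# one row of metrics for a probability matrix
metric_row <- function(pr, labels, tasks, bin_edges, n_bins,
                       decision_threshold, score = NULL, score_thresholds = NULL) {
  cls <- max.col(pr, ties.method = "first") - 1L
  row <- c(accuracy4 = mean(cls == labels))
  for (t in tasks) {
    idx <- match(t, bin_edges)
    pos <- as.integer(labels < idx)
    gp <- group_probability(pr, t, bin_edges)
    decisions <- if (!is.null(score) && !is.null(score_thresholds))
      as.integer(score >= score_thresholds[paste0("lt", t)]) else NULL
    bm <- suppressWarnings(binary_metrics(gp, pos, decision_threshold, decisions))
    e <- ece(pmin(pmax(gp, 0), 1), pos, n_bins)
    names(bm) <- paste0(names(bm), "_lt", t)
    row <- c(row, bm, setNames(e, paste0("ece_lt", t)))
  }
  row["ece"] <- row[paste0("ece_lt", tasks[1])]  # headline: the <30 task
  row
}

#' Evaluate a model on a held-out cohort
#'
#' Computes the full metric suite: 4-way accuracy on the argmax category and,
#' for each grouped binary task (`TTD < t` vs `>= t`), accuracy, F1, PPV,
#' NPV, ROC-AUC, PR-AUC and ECE on the summed grouped probability. The
#' headline ECE is the `< 30` task's. For an ensemble, every member is
#' evaluated and metrics are reported as mean +/- sd across members.
#'
#' @param model a fitted [ttd_fit()] model, a [ttd_fit_ensemble()] ensemble,
#'   or a bare probability matrix (rows = patients of `test`).
#' @param test the evaluation [ttd_cohort()] or [prepare_cohort()] result.
#' @param tasks binary-task thresholds (must be bin edges).
#' @param bin_edges label bin edges.
#' @param n_bins calibration bins for the ECE.
#' @param decision_threshold hard-decision probability cut.
#' @return An object of class `ttd_metrics`: `per_member` (matrix of metric
#'   rows), `mean`, `sd`, `n`, `calibration` (curve for the headline task of
#'   the first member).
#' @export
evaluate_model <- function(model, test, tasks = c(30, 60, 120),
                           bin_edges = c(30, 60, 120), n_bins = 10,
                           decision_threshold = 0.5) {
  if (inherits(model, "ttd_model")) bin_edges <- model$bin_edges
  if (inherits(model, "ttd_ensemble")) bin_edges <- model$members[[1]]$bin_edges
  if (!all(tasks %in% bin_edges)) stop("every task must be one of the bin edges")
  prepared <- if (inherits(test, "ttd_prepared")) test else {
    ref <- if (inherits(model, "ttd_ensemble")) model$members[[1]] else model
    if (inherits(ref, "ttd_model")) prepare_newdata(ref, test)
    else stop("with a bare probability matrix, `test` must be a prepared cohort")
  }
  if (length(prepared) == 0) stop("empty test cohort")
  labels <- prepared$labels

  prob_list <- if (inherits(model, "ttd_ensemble")) {
    lapply(model$members, predict, newdata = prepared, type = "prob")
  } else if (inherits(model, "ttd_model")) {
    list(predict(model, prepared, type = "prob"))
  } else {
    stopifnot(is.matrix(model), nrow(model) == length(labels))
    list(model)
  }
  get_score <- function(m, pr) {
    if (inherits(m, "ttd_model") && m$kind == "criteria")
      list(score = attr(predict_tabular(m, prepared), "score"),
           thr = m$thresholds)
    else list(score = NULL, thr = NULL)
  }
  members <- if (inherits(model, "ttd_ensemble")) model$members
             else if (inherits(model, "ttd_model")) list(model) else list(NULL)

  rows <- do.call(rbind, lapply(seq_along(prob_list), function(i) {
    sc <- if (!is.null(members[[min(i, length(members))]]))
      get_score(members[[min(i, length(members))]], prob_list[[i]])
    else list(score = NULL, thr = NULL)
    metric_row(prob_list[[i]], labels, tasks, bin_edges, n_bins,
               decision_threshold, sc$score, sc$thr)
  }))

  gp1 <- group_probability(prob_list[[1]], tasks[1], bin_edges)
  calib <- calibration_curve(pmin(pmax(gp1, 0), 1),
                             as.integer(labels < match(tasks[1], bin_edges)),
                             n_bins)
  structure(list(per_member = rows,
                 mean = colMeans(rows),
                 sd = if (nrow(rows) > 1) apply(rows, 2, sd) else
                   setNames(rep(0, ncol(rows)), colnames(rows)),
                 n = length(labels), tasks = tasks, bin_edges = bin_edges,
                 calibration = calib,
                 kind = if (inherits(model, "ttd_ensemble")) model$kind
                        else if (inherits(model, "ttd_model")) model$kind
                        else "probabilities"),
            class = "ttd_metrics")
}

#' @export
print.ttd_metrics <- function(x, digits = 3, ...) {
  cat("Evaluation of", x$kind, "on", x$n, "patients",
      if (nrow(x$per_member) > 1)
        paste0("(", nrow(x$per_member), " ensemble members, mean +/- sd)"),
      "\n")
  show <- c("accuracy4",
            as.vector(t(outer(c("accuracy", "roc_auc", "pr_auc", "f1"),
                              paste0("_lt", x$tasks), paste0))), "ece")
  show <- intersect(show, names(x$mean))
  for (nm in show)
    cat(sprintf("  %-18s %.*f +/- %.*f\n", nm, digits, x$mean[nm],
                digits, x$sd[nm]))
  invisible(x)
}
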