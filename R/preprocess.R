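#' Convert TTD minutes to the ordinal category
#'
#' Bins are half-open `[lo, hi)`: with the default edges (30, 60, 120) a TTD
#' of exactly 30 minutes falls in category 1 and exactly 120 minutes in
#' category 3. The category is the number of edges less than or equal to the
#' TTD.
#'
#' @param ttd_minutes positive numeric vector (minutes from extubation to
#'   circulatory death).
#' @param bin_edges strictly increasing positive edges in minutes; the
#'   default `c(30, 60, 120)` gives 4 categories, the extended option
#'   `c(30, 60, 120, 180, 240)` gives 6.
#' @return Integer categories in `0:(length(bin_edges))`.
#' @examples
#' categorize_ttd(c(7.15, 30, 120, 121))  # 0 1 3 3
#' @export
categorize_ttd <- function(ttd_minutes, bin_edges = c(30, 60, 120)) {
  if (any(!is.finite(ttd_minutes)) || any(ttd_minutes <= 0))
    stop("ttd_minutes must be positive and finite")
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE) ||
      any(bin_edges <= 0))
    stop("bin_edges must be strictly increasing positive values")
  findInterval(ttd_minutes, bin_edges, left.open = FALSE)
}

#' Training-split normalization statistics
#'
#' Per-channel mean and standard deviation of the *observed* (mask = 1)
#' longitudinal values, and per-static mean/sd, computed on the training
#' split only. These are the constants used for mean-fill imputation and
#' z-scoring; computing them on the training split alone prevents information
#' from the evaluation split leaking into preprocessing. Degenerate channels
#' (no spread, or never observed) get sd 1 and are logged via `message()`.
#'
#' @param train_cohort the training [ttd_cohort()].
#' @return An object of class `ttd_norm_stats`.
#' @export
normalization_stats <- function(train_cohort) {
  stopifnot(inherits(train_cohort, "ttd_cohort"), length(train_cohort) > 0)
  vocab <- train_cohort$vocabulary
  k <- vocab_k(vocab)
  ch_names <- vocab$longitudinal_names
  sums <- nums <- sqs <- setNames(numeric(k), ch_names)
  for (r in train_cohort$records) {
    m <- r$series$masks == 1
    v <- r$series$values
    sums <- sums + colSums(v * m, na.rm = TRUE)
    sqs <- sqs + colSums(v^2 * m, na.rm = TRUE)
    nums <- nums + colSums(m)
  }
  mu <- ifelse(nums > 0, sums / pmax(nums, 1), 0)
  va <- ifelse(nums > 1, (sqs - nums * mu^2) / pmax(nums - 1, 1), 0)
  s <- sqrt(pmax(va, 0))
  degenerate <- s < 1e-10
  if (any(degenerate))
    message("normalization_stats: degenerate channel(s) get sd = 1: ",
            paste(ch_names[degenerate], collapse = ", "))
  s[degenerate] <- 1

  smat <- t(vapply(train_cohort$records, function(r) r$static,
                   numeric(vocab_l(vocab))))
  smu <- colMeans(smat, na.rm = TRUE)
  smu[!is.finite(smu)] <- 0
  ssd <- apply(smat, 2, sd, na.rm = TRUE)
  ssd[!is.finite(ssd) | ssd < 1e-10] <- 1
  structure(list(
    channel = data.frame(name = ch_names,
                         kind = unname(vocab$longitudinal_kinds[ch_names]),
                         mean = unname(mu), sd = unname(s),
                         n_obs = unname(nums), stringsAsFactors = FALSE),
    static = data.frame(name = vocab$static_names,
                        kind = unname(vocab$static_kinds),
                        mean = unname(smu), sd = unname(ssd),
                        stringsAsFactors = FALSE),
    n_train = length(train_cohort)), class = "ttd_norm_stats")
}

#' @export
print.ttd_norm_stats <- function(x, ...) {
  cat("Normalization statistics from", x$n_train, "training patients\n")
  print(head(x$channel, 8))
  cat("  ...\n")
  invisible(x)
}

#' Impute missing values in a longitudinal series
#'
#' Per channel: carry the last observed value forward, fill remaining leading
#' gaps backward from the first observation, and fill channels never observed
#' for the patient with the training mean. Masks are left untouched - the
#' model still knows what was actually measured.
#'
#' @param series a [longitudinal_series()] (values `NA` where mask is 0).
#' @param stats [normalization_stats()] from the training split.
#' @return The series with a fully defined value matrix. Idempotent.
#' @export
impute_series <- function(series, stats) {
  v <- series$values
  v[series$masks == 0] <- NA_real_
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    if (anyNA(col)) {
      col <- zoo::na.locf(col, na.rm = FALSE)              # forward fill
      col <- zoo::na.locf(col, fromLast = TRUE, na.rm = FALSE)  # backward fill
      col[is.na(col)] <- stats$channel$mean[j]             # mean fill
      v[, j] <- col
    }
  }
  out <- series
  out$values <- v
  out
}

# z-score a value matrix given channel stats; binary channels untouched.
zscore_channels <- function(v, stats, invert = FALSE) {
  for (j in seq_len(ncol(v))) {
    if (stats$channel$kind[j] == "binary") next
    if (invert) v[, j] <- v[, j] * stats$channel$sd[j] + stats$channel$mean[j]
    else v[, j] <- (v[, j] - stats$channel$mean[j]) / stats$channel$sd[j]
  }
  v
}

#' Z-score (or invert) a series with training statistics
#'
#' Continuous and ordinal channels are standardized to training mean 0 / sd
#' 1; binary channels are left untouched. `denormalize_series()` is the exact
#' inverse given the same statistics.
#'
#' @param series a [longitudinal_series()] (typically already imputed).
#' @param stats [normalization_stats()] from the training split.
#' @export
normalize_series <- function(series, stats) {
  out <- series
  out$values <- zscore_channels(series$values, stats)
  out
}

#' @rdname normalize_series
#' @export
denormalize_series <- function(series, stats) {
  out <- series
  out$values <- zscore_channels(series$values, stats, invert = TRUE)
  out
}

#' Temporal train/test split
#'
#' Patients with `era_year < cutoff_year` form the training cohort; patients
#' with `era_year >= cutoff_year` (the first test year) are held out for
#' evaluation. This respects practice drift: the model is always evaluated on
#' later patients than it was trained on.
#'
#' @param cohort a [ttd_cohort()].
#' @param cutoff_year first test year (default 2021).
#' @return `list(train =, test =)` of disjoint, exhaustive cohorts.
#' @export
temporal_split <- function(cohort, cutoff_year = 2021) {
  yr <- cohort_years(cohort)
  tr <- yr < cutoff_year
  if (!any(tr)) stop("temporal_split: training side is empty (no patients before ",
                     cutoff_year, ")")
  if (all(tr)) stop("temporal_split: test side is empty (no patients in or after ",
                    cutoff_year, ")")
  list(train = cohort[which(tr)], test = cohort[which(!tr)])
}

#' Drop the final pre-extubation horizon from a series
#'
#' Keeps only observations at least `horizon_min` minutes before extubation
#' (time <= -horizon_min), emulating a model that must predict well before
#' withdrawal of support (e.g. `horizon_min = 720` for the 12-hour early
#' prediction variant). Returns `NULL` when nothing remains, so callers can
#' flag the patient.
#'
#' @param series a [longitudinal_series()].
#' @param horizon_min positive horizon in minutes.
#' @return The truncated series, or `NULL` if no observation is left.
#' @export
truncate_history <- function(series, horizon_min) {
  stopifnot(horizon_min > 0)
  keep <- series$times <= -horizon_min
  if (!any(keep)) return(NULL)
  longitudinal_series(series$times[keep],
                      series$values[keep, , drop = FALSE],
                      series$masks[keep, , drop = FALSE])
}

#' Prepare a cohort for modelling
#'
#' Applies (optionally) history truncation, then imputation, then z-scoring
#' with training statistics, and assembles per patient the model-ready
#' tensors: filled value matrix, observation mask, inter-observation gaps in
#' hours (capped at `gap_cap_min`), normalized statics, and the TTD label.
#'
#' @param cohort a [ttd_cohort()].
#' @param stats [normalization_stats()] computed on the *training* cohort.
#' @param bin_edges TTD bin edges (minutes).
#' @param normalize z-score values and statics? (z-scoring is a numerical
#'   convenience for the neural models, not part of the clinical definition;
#'   disable to feed raw values).
#' @param horizon_min `NULL` for the full history, or a positive number of
#'   minutes to truncate via [truncate_history()]. Patients with no
#'   observation left are dropped with a warning.
#' @param gap_cap_min ceiling on a single inter-observation gap as seen by the
#'   model (minutes); longer gaps are integrated for the capped duration.
#' @return An object of class `ttd_prepared`: a list with `patients` (one
#'   entry per patient: `patient_id`, `times`, `X`, `M`, `dt_hours`, `s`,
#'   `label`), plus `ids`, `labels`, `ttd_minutes`, `stats`, `vocabulary`,
#'   `bin_edges`.
#' @export
prepare_cohort <- function(cohort, stats, bin_edges = c(30, 60, 120),
                           normalize = TRUE, horizon_min = NULL,
                           gap_cap_min = 1440) {
  stopifnot(inherits(cohort, "ttd_cohort"), inherits(stats, "ttd_norm_stats"))
  dropped <- character()
  pts <- list()
  for (r in cohort$records) {
    ser <- r$series
    if (!is.null(horizon_min)) {
      ser <- truncate_history(ser, horizon_min)
      if (is.null(ser)) { dropped <- c(dropped, r$patient_id); next }
    }
    ser <- impute_series(ser, stats)
    if (normalize) ser <- normalize_series(ser, stats)
    s <- r$static
    s[is.na(s)] <- stats$static$mean[is.na(s)]
    if (normalize) {
      cont <- stats$static$kind != "binary"
      s[cont] <- (s[cont] - stats$static$mean[cont]) / stats$static$sd[cont]
    }
    dt <- c(0, diff(ser$times)) / 60
    dt <- pmin(dt, gap_cap_min / 60)
    pts[[length(pts) + 1L]] <- list(
      patient_id = r$patient_id, times = ser$times,
      X = unname(ser$values), M = unname(ser$masks), dt_hours = dt,
      s = unname(s), label = categorize_ttd(r$ttd_minutes, bin_edges),
      ttd_minutes = r$ttd_minutes)
  }
  if (length(dropped))
    warning(length(dropped), " patient(s) had no observation before the ",
            horizon_min, "-minute horizon and were dropped", call. = FALSE)
  if (!length(pts)) stop("no patients left after preparation")
  structure(list(
    patients = pts,
    ids = vapply(pts, `[[`, "", "patient_id"),
    labels = vapply(pts, `[[`, 0L, "label"),
    ttd_minutes = vapply(pts, `[[`, 0, "ttd_minutes"),
    stats = stats, vocabulary = cohort$vocabulary,
    bin_edges = bin_edges, normalize = normalize,
    horizon_min = horizon_min, gap_cap_min = gap_cap_min),
    class = "ttd_prepared")
}

#' @export
print.ttd_prepared <- function(x, ...) {
  cat("Prepared cohort:", length(x$patients), "patients,",
      length(x$bin_edges) + 1, "TTD categories\n")
  invisible(x)
}

#' @export
length.ttd_prepared <- function(x) length(x$patients)
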