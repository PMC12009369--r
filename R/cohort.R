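#' Irregular longitudinal series
#'
#' One patient's pre-extubation history: observation times in minutes relative
#' to terminal extubation (all <= 0, 0 = extubation), a value matrix with one
#' column per vocabulary channel, and a 0/1 observation mask of the same
#' shape. `values[i, j]` is only meaningful where `masks[i, j] == 1`;
#' unobserved entries are `NA` until imputation.
#'
#' @param times numeric vector of observation times (minutes, <= 0), strictly
#'   increasing.
#' @param values n x k numeric matrix; columns must be named after the
#'   longitudinal channels.
#' @param masks n x k matrix of 0/1 observation indicators.
#' @return An object of class `ttd_series`.
#' @export
longitudinal_series <- function(times, values, masks) {
  values <- as.matrix(values); masks <- as.matrix(masks)
  n <- length(times)
  if (n < 1) stop("a longitudinal series needs at least one observation row")
  if (nrow(values) != n || nrow(masks) != n || ncol(values) != ncol(masks))
    stop("times, values and masks have inconsistent shapes")
  if (is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (any(times > 0)) stop("observation times must be <= 0 (minutes before extubation)")
  if (!all(masks %in% c(0, 1))) stop("masks must be 0/1")
  if (any(rowSums(masks) == 0))
    stop("every observation row must have at least one observed channel")
  if (any(is.na(values[masks == 1])))
    stop("masked-in values must not be NA")
  structure(list(times = as.numeric(times), values = values, masks = masks),
            class = "ttd_series")
}

#' @export
print.ttd_series <- function(x, ...) {
  cat(sprintf("Longitudinal series: %d observation rows, %d channels, span %.1f min\n",
              length(x$times), ncol(x$values), diff(range(x$times))))
  invisible(x)
}

#' Single patient record
#'
#' @param patient_id character scalar, unique within a cohort.
#' @param static named numeric vector of static variables aligned to the
#'   vocabulary's `static_names`.
#' @param series a [longitudinal_series()].
#' @param ttd_minutes time from terminal extubation to circulatory death,
#'   minutes, strictly positive.
#' @param era_year calendar year of the extubation; used by [temporal_split()].
#' @return An object of class `ttd_record`.
#' @export
patient_record <- function(patient_id, static, series, ttd_minutes, era_year) {
  stopifnot(length(patient_id) == 1, inherits(series, "ttd_series"))
  if (!is.finite(ttd_minutes) || ttd_minutes <= 0)
    stop("ttd_minutes must be a positive number")
  if (is.na(era_year)) stop("era_year is required (temporal split)")
  structure(list(patient_id = as.character(patient_id),
                 static = static, series = series,
                 ttd_minutes = as.numeric(ttd_minutes),
                 era_year = as.integer(era_year)),
            class = "ttd_record")
}

#' Patient cohort
#'
#' A list of [patient_record()]s sharing one [ttd_vocabulary()].
#'
#' @param records list of `ttd_record`s with unique `patient_id`s.
#' @param vocabulary the shared channel vocabulary.
#' @param provenance `"synthetic"` or `"file"`.
#' @return An object of class `ttd_cohort`.
#' @export
ttd_cohort <- function(records, vocabulary, provenance = c("synthetic", "file")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(vocabulary, "ttd_vocabulary"))
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicated patient_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  k <- vocab_k(vocabulary)
  for (r in records) {
    if (ncol(r$series$values) != k)
      stop("record ", r$patient_id, " has ", ncol(r$series$values),
           " channels; vocabulary has ", k)
  }
  structure(list(records = records, vocabulary = vocabulary,
                 provenance = provenance),
            class = "ttd_cohort")
}

#' @export
print.ttd_cohort <- function(x, ...) {
  nobs <- vapply(x$records, function(r) length(r$series$times), 0L)
  cat(sprintf("TTD cohort (%s): %d patients, %d channels, %d-%d obs rows/patient (median %d)\n",
              x$provenance, length(x$records), vocab_k(x$vocabulary),
              min(nobs), max(nobs), as.integer(median(nobs))))
  invisible(x)
}

#' @export
length.ttd_cohort <- function(x) length(x$records)

#' Subset a cohort by patient index or id
#'
#' @param x a `ttd_cohort`.
#' @param i integer/logical index or character patient ids.
#' @param ... unused.
#' @export
`[.ttd_cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, cohort_ids(x))
  ttd_cohort(x$records[i], x$vocabulary, x$provenance)
}

#' Patient ids of a cohort
#' @param cohort a `ttd_cohort`.
#' @export
cohort_ids <- function(cohort) vapply(cohort$records, `[[`, "", "patient_id")

#' TTD in minutes for every patient
#' @param cohort a `ttd_cohort`.
#' @export
cohort_ttd <- function(cohort) vapply(cohort$records, `[[`, 0, "ttd_minutes")

# era years
cohort_years <- function(cohort) vapply(cohort$records, `[[`, 0L, "era_year")

## ---------------------------------------------------------------------------
## On-disk format: three UTF-8 CSVs + vocabulary.yaml
##   static.csv:       patient_id, variable, value
##   longitudinal.csv: patient_id, time_min, variable, value
##   outcomes.csv:     patient_id, ttd_minutes, era_year
## ---------------------------------------------------------------------------

#' Read a cohort from the long-format CSV dialect
#'
#' Longitudinal rows are grouped per patient, time-sorted, and pivoted to one
#' row per distinct time with an observation mask. Duplicate
#' (patient, time, variable) rows keep the last occurrence (logged via
#' `message()`). Patients present in the data but missing from `outcomes.csv`
#' are skipped with a warning; patients with an outcome but zero longitudinal
#' rows are rejected with a warning.
#'
#' @param static_path,longitudinal_path,outcomes_path CSV file paths (header
#'   row required, UTF-8).
#' @param vocabulary a [ttd_vocabulary()]; every `variable` value in the files
#'   must be one of its names.
#' @return A [ttd_cohort()] with provenance `"file"`.
#' @examples
#' # a small synthetic cohort in the on-disk dialect ships with the package
#' dir <- system.file("extdata", "example_cohort", package = "ttdcast")
#' co <- read_cohort_dir(dir)
#' co
#' @export
read_cohort <- function(static_path, longitudinal_path, outcomes_path,
                        vocabulary = default_vocabulary()) {
  sta <- read.csv(static_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  lon <- read.csv(longitudinal_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  out <- read.csv(outcomes_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(file, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  need(sta, c("patient_id", "variable", "value"), static_path)
  need(lon, c("patient_id", "time_min", "variable", "value"), longitudinal_path)
  need(out, c("patient_id", "ttd_minutes", "era_year"), outcomes_path)
  build_cohort_from_long(sta, lon, out, vocabulary, provenance = "file")
}

# Shared builder used by read_cohort() and permutation_importance(); takes the
# three long-format data frames already in memory.
build_cohort_from_long <- function(sta, lon, out, vocabulary,
                                   provenance = "file", quiet = FALSE) {
  k <- vocab_k(vocabulary)
  bad <- !(lon$variable %in% vocabulary$longitudinal_names)
  if (any(bad))
    stop("longitudinal row ", which(bad)[1], ": unknown variable '",
         lon$variable[which(bad)[1]], "'")
  bad_s <- !(sta$variable %in% vocabulary$static_names)
  if (any(bad_s))
    stop("static row ", which(bad_s)[1], ": unknown variable '",
         sta$variable[which(bad_s)[1]], "'")

  # de-duplicate (patient, time, variable): keep last
  key <- paste(lon$patient_id, lon$time_min, lon$variable, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    if (!quiet)
      message("read_cohort: ", ndup,
              " duplicated (patient, time, variable) row(s); keeping last")
    lon <- lon[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }

  have_long <- unique(lon$patient_id)
  no_outcome <- setdiff(unique(c(have_long, sta$patient_id)), out$patient_id)
  if (length(no_outcome))
    warning(length(no_outcome), " patient(s) without outcome row skipped: ",
            paste(head(no_outcome, 5), collapse = ", "), call. = FALSE)
  no_series <- setdiff(out$patient_id, have_long)
  if (length(no_series))
    warning(length(no_series), " patient(s) with zero longitudinal rows rejected: ",
            paste(head(no_series, 5), collapse = ", "), call. = FALSE)
  keep <- intersect(out$patient_id, have_long)
  if (!length(keep)) stop("no patient has both longitudinal data and an outcome")

  lon_split <- split(lon[c("time_min", "variable", "value")], lon$patient_id)
  sta_split <- split(sta[c("variable", "value")], sta$patient_id)
  out <- out[match(keep, out$patient_id), , drop = FALSE]

  records <- vector("list", length(keep))
  chan_idx <- setNames(seq_len(k), vocabulary$longitudinal_names)
  for (i in seq_along(keep)) {
    pid <- keep[i]
    li <- lon_split[[pid]]
    tms <- sort(unique(li$time_min))
    vals <- matrix(NA_real_, length(tms), k,
                   dimnames = list(NULL, vocabulary$longitudinal_names))
    msk <- matrix(0, length(tms), k,
                  dimnames = list(NULL, vocabulary$longitudinal_names))
    ri <- match(li$time_min, tms)
    ci <- chan_idx[li$variable]
    vals[cbind(ri, ci)] <- li$value
    msk[cbind(ri, ci)] <- 1
    svec <- setNames(rep(NA_real_, vocab_l(vocabulary)), vocabulary$static_names)
    si <- sta_split[[pid]]
    if (!is.null(si)) svec[si$variable] <- si$value
    records[[i]] <- patient_record(
      patient_id = pid, static = svec,
      series = longitudinal_series(tms, vals, msk),
      ttd_minutes = out$ttd_minutes[i], era_year = out$era_year[i])
  }
  ttd_cohort(records, vocabulary, provenance = provenance)
}

# Inverse of build_cohort_from_long(): long-format data frames for a cohort.
cohort_to_long <- function(cohort) {
  recs <- cohort$records
  lon <- do.call(rbind, lapply(recs, function(r) {
    obs <- which(r$series$masks == 1, arr.ind = TRUE)
    data.frame(patient_id = r$patient_id,
               time_min = r$series$times[obs[, 1]],
               variable = colnames(r$series$values)[obs[, 2]],
               value = r$series$values[obs],
               stringsAsFactors = FALSE)
  }))
  sta <- do.call(rbind, lapply(recs, function(r) {
    data.frame(patient_id = r$patient_id, variable = names(r$static),
               value = unname(r$static), stringsAsFactors = FALSE)
  }))
  out <- data.frame(patient_id = cohort_ids(cohort),
                    ttd_minutes = cohort_ttd(cohort),
                    era_year = cohort_years(cohort),
                    stringsAsFactors = FALSE)
  list(static = sta, longitudinal = lon, outcomes = out)
}

#' Write a cohort to a directory
#'
#' Emits `static.csv`, `longitudinal.csv`, `outcomes.csv` and
#' `vocabulary.yaml` such that [read_cohort()] reproduces the cohort up to row
#' order (the round trip is exact on ids, times, observed values, masks,
#' statics, TTD and era year).
#'
#' @param cohort a non-empty [ttd_cohort()].
#' @param dir output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ttd_cohort"))
  if (length(cohort) == 0) stop("refusing to write an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lf <- cohort_to_long(cohort)
  wr <- function(df, f)
    write.csv(df, file.path(dir, f), row.names = FALSE, fileEncoding = "UTF-8")
  wr(lf$static, "static.csv")
  wr(lf$longitudinal, "longitudinal.csv")
  wr(lf$outcomes, "outcomes.csv")
  write_vocabulary(cohort$vocabulary, file.path(dir, "vocabulary.yaml"))
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#' @param dir directory containing the four cohort files.
#' @export
read_cohort_dir <- function(dir) {
  read_cohort(file.path(dir, "static.csv"),
              file.path(dir, "longitudinal.csv"),
              file.path(dir, "outcomes.csv"),
              read_vocabulary(file.path(dir, "vocabulary.yaml")))
}
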