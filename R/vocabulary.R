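#' Channel vocabulary
#'
#' The vocabulary fixes the identity, order, and value kind of every input
#' channel. Order matters: the model input dimension and the meaning of each
#' weight column depend on it, so a vocabulary is persisted alongside any
#' cohort or fitted model.
#'
#' @param longitudinal_names character vector of longitudinal channel names.
#' @param static_names character vector of static variable names.
#' @param longitudinal_kinds value kind per longitudinal channel, each one of
#'   `"continuous"`, `"ordinal"` or `"binary"`. Binary channels are never
#'   z-scored.
#' @param static_kinds value kind per static variable.
#' @param encodings named list recording how categorical variables were coded
#'   as 0/1 (e.g. `list(sex = c(male = 0, female = 1))`). Persisted so that a
#'   written cohort is self-describing.
#'
#' @return An object of class `ttd_vocabulary`.
#' @seealso [default_vocabulary()]
#' @export
ttd_vocabulary <- function(longitudinal_names, static_names,
                           longitudinal_kinds = rep("continuous", length(longitudinal_names)),
                           static_kinds = rep("continuous", length(static_names)),
                           encodings = list()) {
  longitudinal_names <- as.character(longitudinal_names)
  static_names <- as.character(static_names)
  stopifnot(length(longitudinal_names) >= 1, length(static_names) >= 1,
            length(longitudinal_kinds) == length(longitudinal_names),
            length(static_kinds) == length(static_names))
  kinds_ok <- c("continuous", "ordinal", "binary")
  if (!all(longitudinal_kinds %in% kinds_ok) || !all(static_kinds %in% kinds_ok))
    stop("value kinds must be one of: ", paste(kinds_ok, collapse = ", "))
  nm <- c(longitudinal_names, static_names)
  if (anyDuplicated(nm))
    stop("duplicated variable name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(
    longitudinal_names = longitudinal_names,
    static_names = static_names,
    longitudinal_kinds = setNames(longitudinal_kinds, longitudinal_names),
    static_kinds = setNames(static_kinds, static_names),
    encodings = encodings
  ), class = "ttd_vocabulary")
}

#' Default DCD channel vocabulary
#'
#' The 25 longitudinal channels (vitals, ventilation settings, blood gases,
#' labs, neurological assessments, and vasoactive/endocrine infusions) and 5
#' static variables used throughout the package. Reflexes are coded
#' present/absent (binary); the Glasgow Coma Scale is an integer score fed to
#' the model numeric-as-recorded.
#'
#' @return A `ttd_vocabulary` with k = 25 longitudinal and 5 static names.
#' @examples
#' v <- default_vocabulary()
#' length(v$longitudinal_names)  # 25
#' @export
default_vocabulary <- function() {
  lon <- c(
    bnp = "continuous", carboxyhemoglobin = "continuous",
    corneal_reflex = "binary", fio2 = "continuous", gag_reflex = "binary",
    gcs = "ordinal", hemoglobin = "continuous", lactate = "continuous",
    map = "continuous", methemoglobin = "continuous",
    o2_hemoglobin = "continuous", pco2 = "continuous", peep = "continuous",
    ph = "continuous", po2 = "continuous", pulse = "continuous",
    respirations = "continuous", spo2 = "continuous",
    troponin_i = "continuous", troponin_t = "continuous",
    dopamine = "continuous", epinephrine = "continuous",
    levothyroxine = "continuous", lidocaine = "continuous",
    norepinephrine = "continuous")
  sta <- c(age = "continuous", bmi = "continuous", dialysis = "binary",
           sex = "binary", weight = "continuous")
  ttd_vocabulary(
    longitudinal_names = names(lon), static_names = names(sta),
    longitudinal_kinds = unname(lon), static_kinds = unname(sta),
    encodings = list(sex = c(male = 0, female = 1),
                     dialysis = c(no = 0, yes = 1),
                     corneal_reflex = c(absent = 0, present = 1),
                     gag_reflex = c(absent = 0, present = 1)))
}

#' @export
print.ttd_vocabulary <- function(x, ...) {
  cat("Channel vocabulary:", length(x$longitudinal_names),
      "longitudinal +", length(x$static_names), "static variables\n")
  cat("  longitudinal:", paste(x$longitudinal_names, collapse = ", "), "\n")
  cat("  static:      ", paste(x$static_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a vocabulary as YAML
#'
#' @param vocabulary a `ttd_vocabulary`.
#' @param path file path of the YAML file.
#' @return `read_vocabulary()` returns a `ttd_vocabulary`;
#'   `write_vocabulary()` returns `path` invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "ttd_vocabulary"))
  yaml::write_yaml(list(
    longitudinal = lapply(seq_along(vocabulary$longitudinal_names), function(i)
      list(name = vocabulary$longitudinal_names[i],
           kind = unname(vocabulary$longitudinal_kinds[i]))),
    static = lapply(seq_along(vocabulary$static_names), function(i)
      list(name = vocabulary$static_names[i],
           kind = unname(vocabulary$static_kinds[i]))),
    encodings = lapply(vocabulary$encodings, as.list)
  ), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  y <- yaml::read_yaml(path)
  enc <- lapply(y$encodings, function(e) unlist(e))
  ttd_vocabulary(
    longitudinal_names = vapply(y$longitudinal, `[[`, "", "name"),
    static_names = vapply(y$static, `[[`, "", "name"),
    longitudinal_kinds = vapply(y$longitudinal, `[[`, "", "kind"),
    static_kinds = vapply(y$static, `[[`, "", "kind"),
    encodings = enc)
}

# number of longitudinal channels
vocab_k <- function(vocabulary) length(vocabulary$longitudinal_names)
# number of static variables
vocab_l <- function(vocabulary) length(vocabulary$static_names)
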