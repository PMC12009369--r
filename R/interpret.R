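## Variable importance and the patient phenoscape: permutation importance on
## the grouped binary tasks, trajectory summarization transforms, 2-D
## embedding of the latent phenotypes, clustering and inter-cluster tests.

# replace channel `ch` of every record by the same channel of a donor record
# given by `perm` (trajectory-level permutation: times, values and masks of
# the channel move together, preserving within-series autocorrelation)
permute_channel <- function(records, ch, perm) {
  donor_obs <- lapply(records, function(r) {
    sel <- r$series$masks[, ch] == 1
    list(times = r$series$times[sel], values = r$series$values[sel, ch])
  })
  out <- records
  for (i in seq_along(records)) {
    r <- records[[i]]
    d <- donor_obs[[perm[i]]]
    v <- r$series$values; m <- r$series$masks; tms <- r$series$times
    v[, ch] <- NA_real_; m[, ch] <- 0
    new_t <- setdiff(d$times, tms)
    if (length(new_t)) {
      k <- ncol(v)
      v <- rbind(v, matrix(NA_real_, length(new_t), k))
      m <- rbind(m, matrix(0, length(new_t), k))
      tms <- c(tms, new_t)
      o <- order(tms)
      tms <- tms[o]; v <- v[o, , drop = FALSE]; m <- m[o, , drop = FALSE]
    }
    ri <- match(d$times, tms)
    v[ri, ch] <- d$values; m[ri, ch] <- 1
    keep <- rowSums(m) > 0
    if (!any(keep)) next  # donor had nothing either; leave record unchanged
    out[[i]]$series <- longitudinal_series(tms[keep], v[keep, , drop = FALSE],
                                           m[keep, , drop = FALSE])
  }
  out
}

#' Permutation variable importance
#'
#' For a longitudinal variable, the entire per-patient trajectory of the
#' channel (times, values and masks together) is reassigned across patients;
#' for a static variable, its value is permuted across patients. The
#' importance is the drop in ROC-AUC of the grouped binary task:
#' `delta = baseline AUC - permuted AUC`, averaged over `n_repeats`
#' permutations. Variables the model does not rely on give deltas centred at
#' zero.
#'
#' @param model a fitted [ttd_fit()] model (or ensemble; first member used).
#' @param cohort the evaluation [ttd_cohort()] (raw, not prepared:
#'   permutation happens before preprocessing so imputation reacts to the
#'   permuted masks).
#' @param variables character vector of variable names (default: all
#'   longitudinal and static variables).
#' @param task grouped binary task threshold in minutes.
#' @param n_repeats permutations per variable.
#' @param seed RNG seed.
#' @param .permutations optional list of explicit permutation vectors (one
#'   per repeat), mainly for testing.
#' @return An object of class `ttd_importance`: data frame with `variable`,
#'   `type`, `delta`, `sd`, `rank` (1 = most important), plus the baseline
#'   AUC as an attribute.
#' @export
permutation_importance <- function(model, cohort, variables = NULL, task = 30,
                                   n_repeats = 5, seed = 1,
                                   .permutations = NULL) {
  if (inherits(model, "ttd_ensemble")) model <- model$members[[1]]
  stopifnot(inherits(model, "ttd_model"), inherits(cohort, "ttd_cohort"))
  vocab <- cohort$vocabulary
  if (is.null(variables))
    variables <- c(vocab$longitudinal_names, vocab$static_names)
  unknown <- setdiff(variables,
                     c(vocab$longitudinal_names, vocab$static_names))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))

  bin_edges <- model$bin_edges
  idx <- match(task, bin_edges)
  if (is.na(idx)) stop("task must be one of the bin edges")
  labels <- categorize_ttd(cohort_ttd(cohort), bin_edges)
  pos <- as.integer(labels < idx)
  auc_of <- function(ch) {
    pr <- predict(model, ch, type = "prob")
    roc_auc_score(group_probability(pr, task, bin_edges), pos)
  }
  baseline <- auc_of(cohort)

  set.seed(seed)
  n <- length(cohort)
  perms <- if (!is.null(.permutations)) .permutations
           else lapply(seq_len(n_repeats), function(i) sample.int(n))

  rows <- lapply(variables, function(v) {
    is_long <- v %in% vocab$longitudinal_names
    aucs <- vapply(perms, function(pp) {
      recs <- if (is_long) {
        permute_channel(cohort$records, match(v, vocab$longitudinal_names), pp)
      } else {
        rr <- cohort$records
        vals <- vapply(rr, function(r) unname(r$static[v]), 0)[pp]
        for (i in seq_along(rr)) rr[[i]]$static[v] <- vals[i]
        rr
      }
      auc_of(ttd_cohort(recs, vocab, cohort$provenance))
    }, 0)
    data.frame(variable = v, type = if (is_long) "longitudinal" else "static",
               delta = baseline - mean(aucs),
               sd = if (length(aucs) > 1) sd(baseline - aucs) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$delta, ties.method = "first")
  attr(out, "baseline_auc") <- baseline
  attr(out, "task") <- task
  class(out) <- c("ttd_importance", "data.frame")
  out
}

#' @export
print.ttd_importance <- function(x, ...) {
  cat("Permutation importance (<", attr(x, "task"), "min task, baseline AUC",
      sprintf("%.3f", attr(x, "baseline_auc")), ")\n")
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a channel trajectory into a scalar
#'
#' Only actually observed values (mask = 1) enter the summary; imputed values
#' never leak in. The transforms follow the phenoscape conventions:
#' * `range`: mean of the five highest observations minus the mean of the
#'   five lowest (with fewer than 5 observations this definition degenerates,
#'   so the fallback is max - min);
#' * `min` / `max`: mean of the five lowest / highest observations (all
#'   values when fewer than 5);
#' * `mean`: plain average.
#'
#' @param series a [longitudinal_series()].
#' @param channel channel name (or column index).
#' @param transform one of `"range"`, `"mean"`, `"min"`, `"max"`.
#' @return A scalar, or `NA` if the channel was never observed.
#' @examples
#' # 10 observations 1..10: range = mean(6:10) - mean(1:5) = 5
#' @export
summarize_channel <- function(series, channel,
                              transform = c("range", "mean", "min", "max")) {
  transform <- match.arg(transform)
  if (is.character(channel)) {
    channel <- match(channel, colnames(series$values))
    if (is.na(channel)) stop("unknown channel name")
  }
  v <- series$values[series$masks[, channel] == 1, channel]
  if (!length(v)) return(NA_real_)
  v <- sort(v)
  n <- length(v)
  topm <- function(x) mean(tail(x, 5))
  botm <- function(x) mean(head(x, 5))
  switch(transform,
         range = if (n < 5) max(v) - min(v) else topm(v) - botm(v),
         mean = mean(v),
         min = botm(v),
         max = topm(v))
}

#' Two-dimensional embedding of latent phenotypes
#'
#' Projects the phenotype matrix to 2-D with a neighborhood-preserving
#' method behind a uniform interface: Kruskal non-metric MDS (default,
#' `MASS::isoMDS`), UMAP (`uwot`, if installed) or PCA. Deterministic for a
#' fixed seed.
#'
#' @param phenotypes numeric matrix (patients x dimensions), >= 10 rows.
#' @param method `"nmds"`, `"umap"` or `"pca"`.
#' @param seed RNG seed.
#' @return Matrix with columns `dim1`, `dim2`, one row per input row.
#' @export
embed_2d <- function(phenotypes, method = c("nmds", "umap", "pca"), seed = 1) {
  method <- match.arg(method)
  phenotypes <- as.matrix(phenotypes)
  n <- nrow(phenotypes)
  if (n < 10) stop("embedding needs at least 10 patients, got ", n)
  set.seed(seed)
  coords <- switch(method,
    nmds = {
      # collapse duplicate rows (zero distances break isoMDS), then map back
      key <- apply(phenotypes, 1, paste, collapse = "\r")
      rep_idx <- match(key, key)
      uniq <- !duplicated(key)
      xu <- phenotypes[uniq, , drop = FALSE]
      if (nrow(xu) < 3) {
        cbind(seq_len(n) * 1e-6, 0)  # fully degenerate input
      } else {
        d <- dist(xu)
        d[d < 1e-12] <- 1e-12
        fit <- MASS::isoMDS(d, y = stats::cmdscale(d, 2), trace = FALSE)
        fit$points[match(rep_idx, which(uniq)), , drop = FALSE]
      }
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("method 'umap' needs the uwot package")
      uwot::umap(phenotypes, n_neighbors = min(15, n - 1), n_threads = 1,
                 n_sgd_threads = 0)
    },
    pca = {
      p <- prcomp(phenotypes, center = TRUE, scale. = FALSE)
      k <- min(2, ncol(p$x))
      cbind(p$x[, 1], if (k > 1) p$x[, 2] else 0)
    })
  coords <- as.matrix(coords)
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(phenotypes)
  coords
}

# parse "channel:transform" / static / "ttd_log" variable specs and compute
# per-patient scalars
phenoscape_variables <- function(cohort, specs) {
  vocab <- cohort$vocabulary
  out <- sapply(specs, function(sp) {
    parts <- strsplit(sp, ":", fixed = TRUE)[[1]]
    if (parts[1] == "ttd_log") {
      log(cohort_ttd(cohort))
    } else if (parts[1] %in% vocab$static_names) {
      vapply(cohort$records, function(r) unname(r$static[parts[1]]), 0)
    } else if (parts[1] %in% vocab$longitudinal_names) {
      tr <- if (length(parts) > 1) parts[2] else "mean"
      vapply(cohort$records, function(r)
        summarize_channel(r$series, parts[1], tr), 0)
    } else stop("unknown phenoscape variable: ", sp)
  })
  colnames(out) <- specs
  out
}

#' Cluster the phenoscape and compare clinical variables across clusters
#'
#' Clusters patients on their latent phenotypes (k-means, not on the 2-D
#' coordinates), then for each requested variable reports per-cluster means
#' and two-sided independent t-test p-values for every cluster pair. An
#' optional TTD filter reproduces the zoomed-in analysis of the short-TTD
#' subgroup.
#'
#' @param phenotypes matrix of latent phenotypes (rows aligned to `cohort`).
#' @param cohort the matching [ttd_cohort()].
#' @param variables variable specs: a channel summary as
#'   `"channel:transform"` (e.g. `"pulse:range"`, `"spo2:min"`), a static
#'   name, or `"ttd_log"`.
#' @param n_clusters number of k-means clusters.
#' @param seed RNG seed for k-means.
#' @param max_ttd optional filter: keep only patients with TTD strictly below
#'   this many minutes before clustering.
#' @return An object of class `ttd_phenoscape`: `cluster` assignments (named
#'   by patient), `means` (variable x cluster), `tests` (variable, pair,
#'   p_value; pairs with a cluster of < 2 members are skipped), `values`.
#' @export
cluster_and_compare <- function(phenotypes, cohort,
                                variables = c("ttd_log", "pulse:range",
                                              "spo2:min", "gcs:mean",
                                              "map:max", "bmi"),
                                n_clusters = 3, seed = 1, max_ttd = NULL) {
  stopifnot(nrow(phenotypes) == length(cohort))
  keep <- if (is.null(max_ttd)) rep(TRUE, length(cohort))
          else cohort_ttd(cohort) < max_ttd
  sub <- cohort[which(keep)]
  ph <- phenotypes[keep, , drop = FALSE]
  if (nrow(ph) < n_clusters * 5)
    stop("need at least ", n_clusters * 5, " patients to cluster, got ", nrow(ph))
  set.seed(seed)
  km <- kmeans(ph, centers = n_clusters, nstart = 10)
  cl <- setNames(km$cluster, cohort_ids(sub))
  vals <- phenoscape_variables(sub, variables)

  means <- matrix(
    unlist(lapply(seq_len(n_clusters), function(cc)
      colMeans(vals[cl == cc, , drop = FALSE], na.rm = TRUE))),
    nrow = ncol(vals),
    dimnames = list(colnames(vals), paste0("cluster", seq_len(n_clusters))))

  pairs <- utils::combn(n_clusters, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    if (sum(cl == a) < 2 || sum(cl == b) < 2) return(NULL)
    do.call(rbind, lapply(colnames(vals), function(v) {
      va <- vals[cl == a, v]; vb <- vals[cl == b, v]
      p <- if (sd(c(va, vb), na.rm = TRUE) < 1e-12) 1 else
        tryCatch(t.test(va, vb)$p.value, error = function(e) NA_real_)
      data.frame(variable = v, pair = paste0(a, "-", b), p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(cluster = cl, means = means, tests = tests, values = vals,
                 n_clusters = n_clusters, max_ttd = max_ttd),
            class = "ttd_phenoscape")
}

#' @export
print.ttd_phenoscape <- function(x, ...) {
  cat("Phenoscape clustering:", x$n_clusters, "clusters over",
      length(x$cluster), "patients",
      if (!is.null(x$max_ttd)) paste0("(TTD < ", x$max_ttd, " min)"), "\n")
  cat("Cluster sizes:", paste(table(x$cluster), collapse = ", "), "\n")
  cat("Per-cluster means:\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Build a phenoscape view of a cohort
#'
#' Convenience wrapper: extracts latent phenotypes, embeds them in 2-D,
#' clusters, and attaches coloring scalars.
#'
#' @param model fitted sequence model (or ensemble).
#' @param cohort evaluation cohort.
#' @param variables coloring/comparison variable specs (see
#'   [cluster_and_compare()]).
#' @param method embedding method for [embed_2d()].
#' @param n_clusters,seed passed through.
#' @param max_ttd optional zoom filter (minutes).
#' @return A data frame (class `ttd_phenoscape_view`) with patient_id,
#'   dim1/dim2, cluster, TTD label and the coloring variables; the
#'   [cluster_and_compare()] result is attached as attribute `"clusters"`.
#' @export
phenoscape_view <- function(model, cohort,
                            variables = c("ttd_log", "pulse:range",
                                          "spo2:min", "gcs:mean",
                                          "map:max", "bmi"),
                            method = "nmds", n_clusters = 3, seed = 1,
                            max_ttd = NULL) {
  ph <- extract_phenotypes(model, cohort)
  cc <- cluster_and_compare(ph, cohort, variables, n_clusters, seed, max_ttd)
  keep <- if (is.null(max_ttd)) rep(TRUE, length(cohort))
          else cohort_ttd(cohort) < max_ttd
  sub <- cohort[which(keep)]
  coords <- embed_2d(ph[keep, , drop = FALSE], method = method, seed = seed)
  bin_edges <- if (inherits(model, "ttd_ensemble")) model$members[[1]]$bin_edges
               else model$bin_edges
  out <- data.frame(patient_id = cohort_ids(sub), coords,
                    cluster = unname(cc$cluster),
                    label = categorize_ttd(cohort_ttd(sub), bin_edges),
                    cc$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "clusters") <- cc
  class(out) <- c("ttd_phenoscape_view", "data.frame")
  out
}

#' @export
plot.ttd_phenoscape_view <- function(x, color = "label", ...) {
  v <- x[[color]]
  pal <- grDevices::hcl.colors(8, "viridis")
  col <- if (is.numeric(v) && length(unique(v)) > 8)
    pal[cut(v, 8, labels = FALSE)] else pal[as.integer(factor(v))]
  graphics::plot(x$dim1, x$dim2, col = col, pch = 19,
                 xlab = "dim 1", ylab = "dim 2",
                 main = paste("patient phenoscape -", color), ...)
  invisible(x)
}
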