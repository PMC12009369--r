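#' Model configuration
#'
#' Architecture and optimization settings for the sequence classifiers. The
#' six sub-networks are: `static` (statics encoder), `ode` (hidden-state
#' vector field), the recurrent cell (GRU for the main model), `long` (final
#' hidden-state encoder), `fusion` (latent-phenotype head) and `cls`
#' (classifier). All MLPs have one tanh hidden layer.
#'
#' @param hidden_dim recurrent hidden-state dimension.
#' @param phenotype_dim dimension of the latent phenotype.
#' @param ode_width,static_width,long_width,fusion_width,classifier_width
#'   hidden widths of the MLPs.
#' @param static_dim,long_dim output dimensions of the static and
#'   longitudinal encoders (fusion input is their concatenation).
#' @param solver fixed-step ODE solver, `"euler"` (default) or `"rk4"`.
#'   Adaptive solvers are deliberately avoided: fixed steps keep runs
#'   deterministic.
#' @param max_step maximum solver step in minutes of model time.
#' @param gap_cap ceiling (minutes) on the model time integrated across one
#'   inter-observation gap; multi-day gaps integrate the capped duration.
#' @param lr,epochs,batch_size Adam learning rate, epoch budget, mini-batch
#'   size.
#' @param val_fraction fraction of training patients held out (split by
#'   patient) for early stopping; 0 disables.
#' @param patience epochs without validation improvement before stopping.
#' @param class_weights `NULL` for plain unweighted cross-entropy (default)
#'   or `"inverse"` for inverse-frequency class weighting.
#' @param h0 `"learned"` (trainable initial state, default) or `"zeros"`.
#' @param time_feature `"delta"` feeds the gap since the previous observation
#'   (hours) to the cell; `"absolute"` feeds the observation time itself.
#' @param n_classes number of TTD categories.
#' @param bin_edges TTD bin edges in minutes.
#' @param seed default RNG seed for initialization and batching.
#' @return A list of class `ttd_model_config`.
#' @export
ttd_config <- function(hidden_dim = 16, phenotype_dim = 8,
                       ode_width = 16, static_width = 16, long_width = 16,
                       fusion_width = 16, classifier_width = 16,
                       static_dim = 8, long_dim = 8,
                       solver = c("euler", "rk4"), max_step = 15,
                       gap_cap = 1440,
                       lr = 0.01, epochs = 30, batch_size = 32,
                       val_fraction = 0.1, patience = 6,
                       class_weights = NULL,
                       h0 = c("learned", "zeros"),
                       time_feature = c("delta", "absolute"),
                       n_classes = 4, bin_edges = c(30, 60, 120),
                       seed = 1) {
  solver <- match.arg(solver)
  h0 <- match.arg(h0)
  time_feature <- match.arg(time_feature)
  stopifnot(hidden_dim > 0, phenotype_dim > 0, max_step > 0, gap_cap > 0,
            n_classes == length(bin_edges) + 1)
  structure(as.list(environment()), class = "ttd_model_config")
}

# Parameter shapes for a given cell type. D = 2k + 1 cell input width.
param_shapes <- function(config, k, l, cell, use_ode) {
  H <- config$hidden_dim; D <- 2 * k + 1
  sh <- list(h0 = c(H, 1))
  if (cell == "gru") {
    for (nm in c("Wz", "Wr", "Wh")) sh[[nm]] <- c(H, D + H)
    for (nm in c("bz", "br", "bh")) sh[[nm]] <- c(H, 1)
  } else if (cell == "lstm") {
    for (nm in c("Wi", "Wf", "Wo", "Wg")) sh[[nm]] <- c(H, D + H)
    for (nm in c("bi", "bf", "bo", "bg")) sh[[nm]] <- c(H, 1)
    sh$c0 <- c(H, 1)
  } else if (cell == "rnn") {
    sh$Wx <- c(H, D + H); sh$bx <- c(H, 1)
  } else stop("unknown cell: ", cell)
  if (use_ode) {
    sh$ode_W1 <- c(config$ode_width, H); sh$ode_b1 <- c(config$ode_width, 1)
    sh$ode_W2 <- c(H, config$ode_width); sh$ode_b2 <- c(H, 1)
  }
  sh$static_W1 <- c(config$static_width, l)
  sh$static_b1 <- c(config$static_width, 1)
  sh$static_W2 <- c(config$static_dim, config$static_width)
  sh$static_b2 <- c(config$static_dim, 1)
  sh$long_W1 <- c(config$long_width, H)
  sh$long_b1 <- c(config$long_width, 1)
  sh$long_W2 <- c(config$long_dim, config$long_width)
  sh$long_b2 <- c(config$long_dim, 1)
  sh$fusion_W1 <- c(config$fusion_width, config$static_dim + config$long_dim)
  sh$fusion_b1 <- c(config$fusion_width, 1)
  sh$fusion_W2 <- c(config$phenotype_dim, config$fusion_width)
  sh$fusion_b2 <- c(config$phenotype_dim, 1)
  sh$cls_W1 <- c(config$classifier_width, config$phenotype_dim)
  sh$cls_b1 <- c(config$classifier_width, 1)
  sh$cls_W2 <- c(config$n_classes, config$classifier_width)
  sh$cls_b2 <- c(config$n_classes, 1)
  sh
}

# Glorot-uniform initialization; biases and initial states start at zero.
init_params <- function(shapes, seed) {
  set.seed(seed)
  out <- list()
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    if (d[2] == 1 || nm %in% c("h0", "c0")) {
      out[[nm]] <- matrix(0, d[1], d[2])
    } else {
      a <- sqrt(6 / (d[1] + d[2]))
      out[[nm]] <- matrix(runif(prod(d), -a, a), d[1], d[2])
    }
  }
  out
}

flatten_params <- function(params) unlist(lapply(params, as.numeric))

unflatten_params <- function(theta, shapes) {
  out <- list(); pos <- 0L
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    n <- prod(d)
    out[[nm]] <- matrix(theta[(pos + 1):(pos + n)], d[1], d[2])
    pos <- pos + n
  }
  out
}

# core-facing config list
core_cfg <- function(config, cell, use_ode, class_weights) {
  list(cell = cell, use_ode = use_ode, solver = config$solver,
       max_step_h = config$max_step / 60,
       class_weights = as.numeric(class_weights))
}

# core-facing patient list (label optional). `dt` always carries the capped
# inter-observation gap used for integration; with time_feature = "absolute"
# a separate `tf` feeds the observation time itself to the cell.
core_patients <- function(prepared, config, with_labels = TRUE) {
  lapply(prepared$patients, function(p) {
    out <- list(X = p$X, M = p$M, dt = p$dt_hours, s = p$s,
                y = if (with_labels) as.integer(p$label) else -1L)
    if (config$time_feature == "absolute") out$tf <- p$times / 60
    out
  })
}
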