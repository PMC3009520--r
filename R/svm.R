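#' SVM configuration
#'
#' Soft-margin kernel SVM settings in the field's conventional notation:
#' `d` = polynomial degree, `g` = RBF width, `c` = error/margin trade-off,
#' `j` = cost factor weighting errors on the positive class. Exactly one
#' kernel-specific parameter is active: `d` for the polynomial kernel
#' `(u . v + 1)^d`, `g` for the RBF kernel `exp(-g |u - v|^2)`.
#'
#' @param kernel `"polynomial"` or `"rbf"`.
#' @param d Polynomial degree (required for `kernel = "polynomial"`).
#' @param g RBF width (required for `kernel = "rbf"`).
#' @param c Trade-off between training error and margin (> 0).
#' @param j Cost factor: weight of positive-class errors relative to
#'   negative-class errors (> 0).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("polynomial", "rbf"), d = NULL, g = NULL,
                       c = 1, j = 1) {
  kernel <- match.arg(kernel)
  if (kernel == "polynomial") {
    if (is.null(d)) stop_parameter("polynomial kernel requires degree d")
    g <- NULL
  } else {
    if (is.null(g)) stop_parameter("rbf kernel requires width g")
    d <- NULL
  }
  if (c <= 0 || j <= 0) stop_parameter("c and j must be positive")
  structure(list(kernel = kernel, d = d, g = g, c = c, j = j),
            class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  par <- if (x$kernel == "polynomial") sprintf("d=%g", x$d) else sprintf("g=%g", x$g)
  cat(sprintf("<svm_config> %s kernel, %s, c=%g, j=%g\n", x$kernel, par, x$c, x$j))
  invisible(x)
}

#' Shipped model presets
#'
#' The six published parameter sets (one per window size x encoding scheme)
#' together with the AUC each model reported. `fadpred_preset()` returns the
#' [svm_config] for one of them; `fadpred_presets()` lists all six.
#'
#' @param w Window size: 15, 17 or 19.
#' @param scheme `"binary"` or `"pssm"`.
#' @return `fadpred_preset()`: an [svm_config]; `fadpred_presets()`: a data
#'   frame with columns `window`, `scheme`, `kernel`, `d`, `g`, `c`, `j`,
#'   `auc_published`.
#' @export
fadpred_presets <- function() {
  data.frame(
    window = c(15L, 15L, 17L, 17L, 19L, 19L),
    scheme = c("binary", "pssm", "binary", "pssm", "binary", "pssm"),
    kernel = c("polynomial", "polynomial", "rbf", "polynomial",
               "polynomial", "polynomial"),
    d = c(4, 5, NA, 4, 3, 5),
    g = c(NA, NA, 0.1, NA, NA, NA),
    c = c(1, 1, 2, 5, 1, 1),
    j = c(1, 1, 1, 1, 1, 1),
    auc_published = c(0.769, 0.878, 0.773, 0.904, 0.770, 0.876),
    stringsAsFactors = FALSE
  )
}

#' @rdname fadpred_presets
#' @export
fadpred_preset <- function(w = 17, scheme = c("pssm", "binary")) {
  scheme <- match.arg(scheme)
  tab <- fadpred_presets()
  row <- tab[tab$window == w & tab$scheme == scheme, ]
  if (nrow(row) != 1L)
    stop_parameter("no preset for window %s / scheme %s", w, scheme)
  if (row$kernel == "polynomial")
    svm_config("polynomial", d = row$d, c = row$c, j = row$j)
  else
    svm_config("rbf", g = row$g, c = row$c, j = row$j)
}

#' Train a kernel SVM on encoded windows
#'
#' Fits a soft-margin SVM (libsvm backend) whose decision function is
#' real-valued (signed margin, positive = interacting). The positive-class
#' cost factor `j` is applied as a class weight, reproducing the
#' asymmetric-cost objective. Deterministic given inputs.
#'
#' @param x Feature matrix (rows = patterns).
#' @param labels 0/1 integer labels, both classes present.
#' @param config An [svm_config].
#' @param scheme Encoding scheme of `x` (`"binary"` or `"pssm"`), recorded so
#'   the model can refuse mismatched feature vectors.
#' @param window_size Window size of `x`, recorded likewise.
#' @param seed Integer; recorded in metadata (the fit itself is
#'   deterministic).
#' @param transform Normalization transform used for PSSM features.
#' @return A `trained_model`.
#' @export
train_svm <- function(x, labels, config, scheme = "binary",
                      window_size = NA_integer_, seed = 1L,
                      transform = "logistic") {
  stopifnot(inherits(config, "svm_config"))
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels))
    stop_parameter("%d feature rows but %d labels", nrow(x), length(labels))
  if (length(unique(labels)) < 2L)
    stop_fadpred("fadpred_training_error", "training data contain a single class")
  y <- factor(labels, levels = c(0L, 1L))
  args <- list(x = x, y = y, scale = FALSE, cost = config$c,
               class.weights = c("0" = 1, "1" = config$j))
  if (config$kernel == "polynomial") {
    # SVM_light's default polynomial form (u.v + 1)^d: unit gamma and coef0
    args <- c(args, list(kernel = "polynomial", degree = config$d,
                         gamma = 1, coef0 = 1))
  } else {
    args <- c(args, list(kernel = "radial", gamma = config$g))
  }
  fit <- withr::with_seed(as.integer(seed), do.call(e1071::svm, args))

  # libsvm orients decision values toward the first label it encounters;
  # normalize so positive class scores high.
  dv <- attr(predict(fit, x[1:min(2L, nrow(x)), , drop = FALSE],
                     decision.values = TRUE), "decision.values")
  flip <- identical(colnames(dv), "0/1")

  structure(list(
    config = config, scheme = scheme,
    window_size = as.integer(window_size),
    fit = fit, flip = flip,
    meta = list(seed = as.integer(seed), n = nrow(x), dim = ncol(x),
                n_pos = sum(labels == 1L), transform = transform,
                fingerprint = dataset_fingerprint(x, labels),
                package_version = as.character(packageVersion("fadpred")))
  ), class = "trained_model")
}

dataset_fingerprint <- function(x, labels) {
  sprintf("n%d_d%d_s%.6g_l%d", nrow(x), ncol(x), sum(x), sum(labels))
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s w=%d, %s kernel (n=%d, dim=%d)\n",
              x$scheme, x$window_size, x$config$kernel, x$meta$n, x$meta$dim))
  invisible(x)
}

check_scheme <- function(model, x, scheme = NULL) {
  if (ncol(x) != model$meta$dim)
    stop_parameter("model expects %d-dimensional vectors, got %d",
                   model$meta$dim, ncol(x))
  if (!is.null(scheme) && !identical(scheme, model$scheme))
    stop_parameter("model was trained on '%s' features, got '%s'",
                   model$scheme, scheme)
}

#' Raw decision values for feature vectors
#'
#' One signed-margin score per row; classification at threshold `t` is
#' `score >= t` = interacting.
#'
#' @param model A `trained_model`.
#' @param x Feature matrix with the model's dimensionality.
#' @param scheme Optional scheme tag to check against the model's.
#' @return Numeric vector of decision values.
#' @export
decision_scores <- function(model, x, scheme = NULL) {
  stopifnot(inherits(model, "trained_model"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  check_scheme(model, x, scheme)
  dv <- attr(predict(model$fit, x, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv)
  if (model$flip) -s else s
}

#' Thresholded residue calls
#'
#' @inheritParams decision_scores
#' @param threshold Decision-value cutoff; by convention swept over
#'   \[-1, +1\], default 0.
#' @return Integer 0/1 vector (1 = predicted interacting).
#' @export
predict_labels <- function(model, x, threshold = 0, scheme = NULL) {
  as.integer(decision_scores(model, x, scheme) >= threshold)
}

#' Persist / restore a trained model
#'
#' The model is serialized as an RDS blob with a JSON sidecar
#' (`<path>.json`) recording configuration, scheme, window size and the
#' normalization transform; loading refuses a sidecar/blob scheme mismatch.
#'
#' @param model A `trained_model`.
#' @param path Output path (conventionally `.rds`).
#' @return `save_model`: invisibly `path`; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  side <- list(scheme = model$scheme, window_size = model$window_size,
               kernel = model$config$kernel,
               d = model$config$d, g = model$config$g,
               c = model$config$c, j = model$config$j,
               transform = model$meta$transform,
               fingerprint = model$meta$fingerprint, seed = model$meta$seed)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model"))
    stop_format("'%s' is not a fadpred model file", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (!identical(side$scheme, model$scheme) ||
        !identical(as.integer(side$window_size), model$window_size))
      stop_consistency("model sidecar disagrees with blob (scheme/window)")
  }
  model
}
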