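#' Grid-search configuration
#'
#' The `(C, gamma)` search lattice in log2 space and the cross-validation
#' settings. Defaults follow the classic coarse grid of the LIBSVM tuning
#' script: `C = 2^-5 ... 2^15` (step 2), `gamma = 2^3 ... 2^-15` (step -2),
#' 5-fold CV. These bounds contain every optimum the method is expected to
#' report (`C` up to 32768, `gamma` down to ~0.13).
#'
#' @param log2C `(start, stop, step)` for log2(C).
#' @param log2gamma `(start, stop, step)` for log2(gamma).
#' @param n_folds Number of CV folds (`>= 2`).
#' @param seed Seed for the fold assignment.
#' @return A `grid_config`.
#' @export
grid_config <- function(log2C = c(-5, 15, 2), log2gamma = c(3, -15, -2),
                        n_folds = 5L, seed = 1L) {
  if (log2C[3] == 0 || log2gamma[3] == 0) stop_flowmrd("grid steps must be nonzero")
  if (n_folds < 2L) stop_flowmrd("n_folds must be >= 2")
  structure(list(log2C = log2C, log2gamma = log2gamma,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "grid_config")
}

# Label-stratified fold assignment: within each class, events are shuffled
# (seeded) and dealt round-robin, so every fold sees leukemic events even at
# extreme class imbalance.
stratified_folds <- function(flags, n_folds, seed) {
  folds <- integer(length(flags))
  with_seed(seed, {
    for (cl in unique(flags)) {
      rows <- which(flags == cl)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  })
  folds
}

svm_fit <- function(x, y01, C, gamma) {
  e1071::svm(x, factor(y01, levels = c(1L, 0L)), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

svm_predict01 <- function(fit, x) {
  as.integer(as.character(stats::predict(fit, x)))
}

# k-fold CV classification accuracy (%) for one (C, gamma) with fixed folds.
cv_accuracy <- function(x, y, folds, C, gamma) {
  n_folds <- max(folds)
  correct <- 0L
  for (k in seq_len(n_folds)) {
    te <- folds == k
    fit <- svm_fit(x[!te, , drop = FALSE], y[!te], C, gamma)
    correct <- correct + sum(svm_predict01(fit, x[te, , drop = FALSE]) == y[te])
  }
  100 * correct / length(y)
}

#' Optimise (C, gamma) by cross-validated grid search
#'
#' Evaluates every `(C, gamma) = (2^a, 2^b)` on the configured log2 lattice
#' by seeded, label-stratified k-fold cross-validation on the (already
#' scaled) training set, and returns the pair with maximal CV accuracy.
#' Ties — common on separable data, where a whole plateau of the grid
#' reaches 100% — break towards larger `C`, then smaller `gamma`: at equal
#' accuracy this prefers the hard margin with the smoothest kernel, which
#' also yields a much sparser (faster-predicting) dual representation.
#'
#' @param ts A scaled `training_set`.
#' @param cfg A [grid_config()].
#' @param verbose Print each grid point's accuracy.
#' @return A `model_params`: list with `C`, `gamma`, `cv_accuracy` (percent)
#'   and the full `grid` (data.frame of every point evaluated).
#' @export
grid_search <- function(ts, cfg = grid_config(), verbose = FALSE) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$flags)) < 2L)
    stop_flowmrd("grid search needs both labels in the training set")
  if (nrow(ts$features) < cfg$n_folds)
    stop_flowmrd("fewer events (%d) than folds (%d)", nrow(ts$features), cfg$n_folds)
  la <- seq(cfg$log2C[1], cfg$log2C[2], by = cfg$log2C[3])
  lb <- seq(cfg$log2gamma[1], cfg$log2gamma[2], by = cfg$log2gamma[3])
  folds <- stratified_folds(ts$flags, cfg$n_folds, cfg$seed)
  grid <- expand.grid(log2C = la, log2gamma = lb, KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$cv_accuracy[i] <- cv_accuracy(ts$features, ts$flags, folds,
                                       2^grid$log2C[i], 2^grid$log2gamma[i])
    if (verbose)
      message(sprintf("log2C=%3g log2g=%4g cv=%.3f%%",
                      grid$log2C[i], grid$log2gamma[i], grid$cv_accuracy[i]))
  }
  best_acc <- max(grid$cv_accuracy)
  cand <- grid[grid$cv_accuracy == best_acc, , drop = FALSE]
  cand <- cand[order(-cand$log2C, cand$log2gamma), , drop = FALSE]
  structure(list(C = 2^cand$log2C[1], gamma = 2^cand$log2gamma[1],
                 cv_accuracy = best_acc, grid = grid),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: C = %g, gamma = %g, CV accuracy = %.2f%%\n",
              x$C, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Train the patient-specific RBF-SVM model
#'
#' Fits a soft-margin binary SVM with kernel
#' `K(u, v) = exp(-gamma * ||u - v||^2)` and penalty `C` on the scaled
#' training features. The returned model embeds the scaling range and
#' channel list, and carries the fitted support vectors, dual coefficients
#' and intercept, so prediction is self-contained (and identical after a
#' save/load round trip).
#'
#' @param ts A scaled `training_set`.
#' @param params A `model_params` (or any list with `C`, `gamma`).
#' @param range The [fit_scaling()] range fitted on the unscaled training
#'   features.
#' @param channels Ordered feature channel names.
#' @return A `patient_model`.
#' @export
train_model <- function(ts, params, range, channels = colnames(ts$features)) {
  stopifnot(inherits(ts, "training_set"), inherits(range, "scaling_range"))
  if (length(unique(ts$flags)) < 2L)
    stop_flowmrd("training needs both labels")
  if (!all(is.finite(ts$features))) stop_flowmrd("non-finite training features")
  fit <- svm_fit(ts$features, ts$flags, params$C, params$gamma)
  # Dual form: f(x) = sum_i coef_i K(sv_i, x) - rho. LIBSVM orients the
  # decision function towards whichever class appears first in the data, so
  # normalise here: after the flip below, f > 0 always means flag 1.
  dv <- attr(stats::predict(fit, ts$features[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (identical(colnames(dv), "0/1")) -1 else 1
  structure(list(params = list(C = params$C, gamma = params$gamma,
                               cv_accuracy = params$cv_accuracy %||% NA_real_),
                 range = range, channels = channels,
                 sv = fit$SV, coefs = flip * as.numeric(fit$coefs),
                 rho = flip * as.numeric(fit$rho)),
            class = "patient_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patient_model <- function(x, ...) {
  cat(sprintf("patient_model: RBF-SVM, C = %g, gamma = %g, %d support vectors\n",
              x$params$C, x$params$gamma, nrow(x$sv)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (is.finite(x$params$cv_accuracy))
    cat(sprintf("  CV accuracy: %.2f%%\n", x$params$cv_accuracy))
  invisible(x)
}

# Decision values from the stored dual representation; chunked so that the
# n_events x n_SV kernel block stays within ~2e7 elements.
rbf_decision <- function(model, x, chunk = NULL) {
  n <- nrow(x)
  if (is.null(chunk))
    chunk <- max(256L, as.integer(2e7 / max(1L, nrow(model$sv))))
  dec <- numeric(n)
  sv <- model$sv
  sv_sq <- rowSums(sv^2)
  g <- model$params$gamma
  for (beg in seq(1L, n, by = chunk)) {
    end <- min(beg + chunk - 1L, n)
    xi <- x[beg:end, , drop = FALSE]
    d2 <- outer(rowSums(xi^2), sv_sq, `+`) - 2 * xi %*% t(sv)
    dec[beg:end] <- exp(-g * pmax(d2, 0)) %*% model$coefs - model$rho
  }
  dec
}

#' Predict the MRD fraction of a follow-up specimen
#'
#' Restricts the specimen to the model's feature channels, applies the
#' embedded saved scaling range, classifies every event with the stored
#' decision function, and reports the leukemic fraction
#' `100 * #(flag 1) / n_events` as a percentage.
#'
#' @param model A `patient_model`.
#' @param specimen An [event_matrix()] (or bare feature matrix with
#'   colnames).
#' @return An `mrd_result`: list with `labels` (integer 0/1 per event),
#'   `leukemic_fraction` (percent) and `n_events`.
#' @export
predict_mrd <- function(model, specimen) {
  stopifnot(inherits(model, "patient_model"))
  vals <- if (inherits(specimen, "event_matrix")) specimen$values else as.matrix(specimen)
  if (nrow(vals) == 0L) stop_flowmrd("cannot predict on an empty specimen")
  missing <- setdiff(model$channels, colnames(vals))
  if (length(missing))
    stop_flowmrd("specimen lacks model channel(s): %s", paste(missing, collapse = ", "))
  x <- apply_scaling(vals[, model$channels, drop = FALSE], model$range)
  labels <- as.integer(rbf_decision(model, x) > 0)
  structure(list(labels = labels,
                 leukemic_fraction = 100 * sum(labels == 1L) / length(labels),
                 n_events = length(labels)),
            class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat(sprintf("mrd_result: %d / %d events leukemic = %.4f%%\n",
              sum(x$labels == 1L), x$n_events, x$leukemic_fraction))
  invisible(x)
}

#' Scatter-plot table of a prediction
#'
#' Returns one `(x, y, label)` row per event on the requested channel pair,
#' on the original (unscaled) intensity scale, for the red/blue
#' leukemic-vs-normal scatter display.
#'
#' @param specimen The [event_matrix()] that was classified.
#' @param result The matching `mrd_result`.
#' @param channel_pair Two channel names, e.g. `c("CD7", "CD117")`.
#' @return A data.frame with columns `x`, `y`, `label` (`"leukemic"` /
#'   `"normal"`).
#' @export
render_prediction <- function(specimen, result, channel_pair = c("CD7", "CD117")) {
  stopifnot(inherits(specimen, "event_matrix"), inherits(result, "mrd_result"))
  missing <- setdiff(channel_pair, specimen$channels$short_name)
  if (length(missing))
    stop_flowmrd("unknown channel(s): %s", paste(missing, collapse = ", "))
  if (nrow(specimen$values) != result$n_events)
    stop_flowmrd("specimen (%d events) does not match result (%d events)",
                 nrow(specimen$values), result$n_events)
  data.frame(x = specimen$values[, channel_pair[1]],
             y = specimen$values[, channel_pair[2]],
             label = ifelse(result$labels == 1L, "leukemic", "normal"),
             stringsAsFactors = FALSE)
}

# ---- Model persistence -----------------------------------------------------

#' Write / read a patient model file
#'
#' Versioned plain-text format holding the kernel parameters, the saved
#' scaling range, the channel list, and the dual representation (support
#' vectors, coefficients, intercept). A reloaded model produces identical
#' predictions.
#'
#' @param model A `patient_model`.
#' @param path File path.
#' @return `path` (writer) or a `patient_model` (reader).
#' @export
write_patient_model <- function(model, path) {
  stopifnot(inherits(model, "patient_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("flowMRD-model v1",
               sprintf("params %.17g %.17g %.17g",
                       model$params$C, model$params$gamma,
                       model$params$cv_accuracy %||% NA_real_),
               paste("channels", paste(model$channels, collapse = " ")),
               sprintf("target %.17g %.17g", model$range$lo, model$range$hi),
               paste("rmin", paste(sprintf("%.17g", model$range$min), collapse = " ")),
               paste("rmax", paste(sprintf("%.17g", model$range$max), collapse = " ")),
               sprintf("rho %.17g", model$rho),
               sprintf("nsv %d", nrow(model$sv))), con)
  writeLines(paste(sprintf("%.17g", model$coefs),
                   apply(model$sv, 1L, function(r)
                     paste(sprintf("%.17g", r), collapse = " "))), con)
  invisible(path)
}

#' @rdname write_patient_model
#' @export
read_patient_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "flowMRD-model"))
    stop_flowmrd("'%s' is not a flowMRD model file", path)
  field <- function(i) strsplit(lines[i], " ", fixed = TRUE)[[1]]
  pr <- as.numeric(field(2)[-1])
  channels <- field(3)[-1]
  tg <- as.numeric(field(4)[-1])
  rmin <- as.numeric(field(5)[-1])
  rmax <- as.numeric(field(6)[-1])
  rho <- as.numeric(field(7)[2])
  nsv <- as.integer(field(8)[2])
  rows <- strsplit(lines[8 + seq_len(nsv)], " ", fixed = TRUE)
  coefs <- as.numeric(vapply(rows, `[[`, character(1), 1L))
  sv <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L), use.names = FALSE)),
               nrow = nsv, byrow = TRUE, dimnames = list(NULL, channels))
  range <- structure(list(min = stats::setNames(rmin, channels),
                          max = stats::setNames(rmax, channels),
                          lo = tg[1], hi = tg[2], channels = channels),
                     class = "scaling_range")
  structure(list(params = list(C = pr[1], gamma = pr[2], cv_accuracy = pr[3]),
                 range = range, channels = channels,
                 sv = sv, coefs = coefs, rho = rho),
            class = "patient_model")
}
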