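test_that("a degenerate single-point grid returns that point with its CV accuracy", {
  ts <- separable_training_set()
  cfg <- grid_config(log2C = c(3, 3, 2), log2gamma = c(-1, -1, -2), seed = 2)
  params <- grid_search(ts, cfg)
  expect_equal(params$C, 2^3)
  expect_equal(params$gamma, 2^-1)
  expect_identical(nrow(params$grid), 1L)
  expect_true(params$cv_accuracy >= 0 && params$cv_accuracy <= 100)
})

test_that("well-separated clouds reach 100% CV accuracy somewhere on the grid", {
  ts <- separable_training_set(gap = 8)
  params <- grid_search(ts, grid_config(log2C = c(-5, 15, 4),
                                        log2gamma = c(3, -15, -4), seed = 1))
  expect_equal(max(params$grid$cv_accuracy), 100)
  expect_equal(params$cv_accuracy, 100)
})

test_that("coin-flip labels give chance-level CV accuracy", {
  set.seed(77)
  X <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("F1", "F2")))
  flags <- rep(0:1, each = 100)[sample.int(200)]
  ts <- structure(list(features = X, flags = as.integer(flags),
                       sources = rep("s", 200)), class = "training_set")
  params <- grid_search(ts, grid_config(log2C = c(1, 1, 2),
                                        log2gamma = c(-1, -1, -2), seed = 4))
  # binomial noise over 200 events: chance 50%, sd ~3.5 points
  expect_gt(params$cv_accuracy, 35)
  expect_lt(params$cv_accuracy, 65)
})

test_that("grid ties break towards larger C then smaller gamma", {
  ts <- separable_training_set(gap = 10)
  params <- grid_search(ts, grid_config(log2C = c(-5, 15, 4),
                                        log2gamma = c(3, -15, -4), seed = 1))
  g <- params$grid
  best <- g[g$cv_accuracy == max(g$cv_accuracy), ]
  best <- best[order(-best$log2C, best$log2gamma), ]
  expect_equal(params$C, 2^best$log2C[1])
  expect_equal(params$gamma, 2^best$log2gamma[1])
  expect_gt(nrow(best), 1)  # the tie is real on separable data
})

test_that("grid search rejects degenerate training sets", {
  ts <- separable_training_set()
  ts$flags <- rep(1L, length(ts$flags))
  expect_error(grid_search(ts), "both labels")
  ts2 <- separable_training_set(n_pos = 2, n_neg = 2)
  expect_error(grid_search(ts2, grid_config(n_folds = 5)), "folds")
})

test_that("stratified folds keep both labels in every fold at extreme imbalance", {
  flags <- c(rep(1L, 10), rep(0L, 990))
  folds <- flowMRD:::stratified_folds(flags, 5L, seed = 3)
  for (k in 1:5) {
    expect_gte(sum(flags[folds == k] == 1L), 2L)
    expect_gte(sum(flags[folds == k] == 0L), 1L)
  }
})

test_that("training a separable set reclassifies itself perfectly", {
  ts <- separable_training_set(gap = 6)
  rng <- fit_scaling(ts)
  ts$features <- apply_scaling(ts$features, rng)
  model <- train_model(ts, list(C = 8, gamma = 0.5), rng, colnames(ts$features))
  # feed back the unscaled coordinates: predict_mrd re-applies the range
  orig <- invert_scaling(ts$features, rng)
  res <- predict_mrd(model, orig)
  expect_identical(res$labels, ts$flags)
  expect_equal(res$leukemic_fraction, 100 * mean(ts$flags == 1L))
})

test_that("identical points with opposite labels train and misclassify one", {
  X <- matrix(c(0.5, 0.5, 0.5, 0.5, -1, -1), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("F1", "F2")))
  ts <- structure(list(features = X, flags = c(1L, 0L, 0L),
                       sources = rep("s", 3)), class = "training_set")
  rng <- structure(list(min = c(F1 = -1, F2 = -1), max = c(F1 = 1, F2 = 1),
                        lo = -1, hi = 1, channels = c("F1", "F2")),
                   class = "scaling_range")
  model <- train_model(ts, list(C = 1, gamma = 1), rng)
  res <- predict_mrd(model, invert_scaling(X, rng))
  expect_identical(sum(res$labels != ts$flags), 1L)
})

test_that("model files round-trip with identical predictions", {
  ts <- separable_training_set(n_pos = 40, n_neg = 80, gap = 5)
  rng <- fit_scaling(ts)
  scaled <- ts
  scaled$features <- apply_scaling(ts$features, rng)
  model <- train_model(scaled, list(C = 32, gamma = 2, cv_accuracy = 99.5), rng)
  set.seed(8)
  probe <- matrix(rnorm(400, sd = 3), ncol = 2,
                  dimnames = list(NULL, c("F1", "F2")))
  before <- predict_mrd(model, probe)
  mp <- withr::local_tempfile(fileext = ".model")
  write_patient_model(model, mp)
  reloaded <- read_patient_model(mp)
  after <- predict_mrd(reloaded, probe)
  expect_identical(after$labels, before$labels)
  expect_equal(after$leukemic_fraction, before$leukemic_fraction)
  expect_equal(reloaded$params$C, 32)
  expect_equal(reloaded$params$cv_accuracy, 99.5)
})

test_that("the stored dual decision matches the backend classifier", {
  # the manual kernel evaluation must reproduce the fitted SVM's own labels,
  # whichever class LIBSVM happened to orient the decision towards
  for (first_class in c(1L, 0L)) {
    ts <- separable_training_set(n_pos = 30, n_neg = 60, gap = 4, seed = 14)
    if (first_class == 0L) {
      o <- order(ts$flags)  # flag 0 rows first
      ts$features <- ts$features[o, ]; ts$flags <- ts$flags[o]
      ts$sources <- ts$sources[o]
    }
    rng <- fit_scaling(ts)
    scaled <- ts
    scaled$features <- apply_scaling(ts$features, rng)
    model <- train_model(scaled, list(C = 4, gamma = 1), rng)
    fit <- flowMRD:::svm_fit(scaled$features, ts$flags, 4, 1)
    probe <- scaled$features
    expect_identical(as.integer(flowMRD:::rbf_decision(model, probe) > 0),
                     flowMRD:::svm_predict01(fit, probe))
  }
})

test_that("MRD fraction is consistent with labels and permutation-invariant", {
  case <- quick_patient(seed = 19, fractions = 0.02)
  ts <- build_training_set(case$diagnosis, case$donors)
  sub <- stratified_sample(ts, 2000, seed = 1)
  rng <- fit_scaling(sub)
  scaled <- sub
  scaled$features <- apply_scaling(sub$features, rng)
  model <- train_model(scaled, list(C = 8, gamma = 0.5), rng)
  sp <- case$followups[[1]]$events
  res <- predict_mrd(model, sp)
  expect_equal(res$leukemic_fraction, 100 * sum(res$labels == 1L) / res$n_events)
  set.seed(3)
  perm <- sample.int(nrow(sp$values))
  sp2 <- event_matrix(sp$values[perm, ], sp$channels, "shuffled")
  res2 <- predict_mrd(model, sp2)
  expect_equal(res2$leukemic_fraction, res$leukemic_fraction)
  expect_identical(res2$labels, res$labels[perm])
})

test_that("render_prediction emits raw-scale coordinates with matching labels", {
  case <- quick_patient(seed = 23, fractions = 0.1)
  sp <- case$followups[[1]]$events
  labels <- as.integer(flowMRD:::is_leukemic_label(case$followups[[1]]$truth_labels))
  res <- structure(list(labels = labels,
                        leukemic_fraction = 100 * mean(labels),
                        n_events = length(labels)), class = "mrd_result")
  tab <- render_prediction(sp, res, c("CD7", "CD117"))
  expect_identical(nrow(tab), res$n_events)
  expect_identical(sum(tab$label == "leukemic"), sum(labels == 1L))
  expect_equal(tab$x, unname(sp$values[, "CD7"]))
  expect_equal(tab$y, unname(sp$values[, "CD117"]))
  expect_error(render_prediction(sp, res, c("CD7", "NOPE")), "NOPE")
  all0 <- res; all0$labels <- rep(0L, res$n_events)
  expect_true(all(render_prediction(sp, all0, c("FSC", "SSC"))$label == "normal"))
})
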