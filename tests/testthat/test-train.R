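test_that("zero epochs leave the model untouched with empty history", {
  set.seed(1)
  model <- build_network(network_spec(base_channels = 1, input_size = 32))
  w_before <- model$nodes[[2]]$params$W
  s <- slice_sample(matrix(runif(32 * 32), 32), matrix(0, 32, 32))
  fit <- train_network(model, list(s), training_config(epochs = 0))
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$model$nodes[[2]]$params$W, w_before)
})

test_that("training is reproducible under a fixed seed", {
  ph <- easy_phantom()
  samples <- prepare_training_samples(list(easy = ph), 32)[1:4]
  losses <- vapply(1:2, function(run) {
    set.seed(11)
    model <- build_network(network_spec(base_channels = 2, input_size = 32))
    fit <- train_network(model, samples,
                         training_config(epochs = 1, seed = 42))
    fit$history$train_loss[1]
  }, numeric(1))
  expect_identical(losses[1], losses[2])
})

test_that("a small model overfits one easy phantom slice", {
  ph <- easy_phantom()
  samples <- prepare_training_samples(list(easy = ph), 32)
  set.seed(3)
  model <- build_network(network_spec(base_channels = 4, input_size = 32))
  fit <- train_network(model, samples[1],
                       training_config(learning_rate = 0.03, epochs = 50,
                                       seed = 3))
  expect_lt(tail(fit$history$train_loss, 1), 0.1)
  # loss went down substantially from its starting point
  expect_lt(tail(fit$history$train_loss, 1),
            fit$history$train_loss[1] / 2)
})

test_that("non-finite losses abort with a diagnostic", {
  set.seed(4)
  model <- build_network(network_spec(base_channels = 1, input_size = 32))
  bad <- slice_sample(matrix(NaN, 32, 32), matrix(0, 32, 32))
  expect_error(
    suppressWarnings(train_network(model, list(bad),
                                   training_config(epochs = 1))),
    "diverged"
  )
})

test_that("cross-validation folds partition subjects exactly once", {
  ids <- sprintf("S%02d", 1:10)
  folds <- cv_folds(ids, n_folds = 5, seed = 3)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), ids)
  expect_identical(folds, cv_folds(ids, 5, seed = 3))
  expect_false(identical(folds, cv_folds(ids, 5, seed = 4)))
  expect_error(cv_folds(ids[1:3], 5), "at least as many")
})

test_that("no subject leaks between train and validation in any fold", {
  # exhaustive membership check across many random seeds
  ids <- sprintf("S%02d", 1:23)
  for (seed in 1:20) {
    folds <- cv_folds(ids, n_folds = 5, seed = seed)
    for (f in seq_along(folds)) {
      train_ids <- setdiff(ids, folds[[f]])
      expect_length(intersect(train_ids, folds[[f]]), 0)
      expect_setequal(union(train_ids, folds[[f]]), ids)
    }
    expect_setequal(unlist(folds), ids)
    expect_equal(sum(lengths(folds)), length(ids))
  }
})

test_that("crossvalidate trains per fold and scores each subject once", {
  phantoms <- generate_phantom_cohort(n_subjects = 5, size = 32,
                                      n_slices = 4, n_notch_slices = 3,
                                      seed = 2)
  samples <- prepare_training_samples(phantoms, 32)
  cfg <- training_config(epochs = 1, n_folds = 5, seed = 2)
  cv <- crossvalidate(samples, cfg,
                      network_spec(base_channels = 1, input_size = 32))
  expect_equal(nrow(cv$per_subject), 5)
  expect_setequal(cv$per_subject$subject_id, names(phantoms))
  expect_equal(sort(unique(cv$per_subject$fold)), 1:5)
  expect_equal(nrow(cv$per_fold), 5)
  expect_true(all(cv$per_subject$dsc >= 0 & cv$per_subject$dsc <= 1))
  expect_equal(cv$summary$mean_dsc, mean(cv$per_subject$dsc))
})

test_that("prediction thresholds probability maps into aligned masks", {
  ph <- easy_phantom()
  # constant-output models: zero head weights, saturated bias
  make_const <- function(bias) {
    set.seed(5)
    m <- build_network(network_spec(base_channels = 1, input_size = 32))
    head_id <- max(which(vapply(m$nodes, function(nd) nd$op == "conv",
                                logical(1))))
    m$nodes[[head_id]]$params$W[] <- 0
    m$nodes[[head_id]]$params$b[] <- bias
    m
  }
  full <- predict_mask(make_const(50), ph$volume)
  expect_true(all(full$labels == 1))
  empty <- predict_mask(make_const(-50), ph$volume)
  expect_true(all(empty$labels == 0))
  expect_equal(empty$geometry, ph$volume$geometry)

  # thresholding equals the elementwise comparison oracle
  model <- tiny_model()
  samples <- prepare_training_samples(list(easy = ph), 32)
  probs <- notchseg:::predict_slices(model, samples)
  pm <- predict_mask(model, ph$volume, threshold = 0.5)
  roi <- vapply(samples, function(s) s$slice_index, integer(1))
  for (k in seq_along(roi)) {
    expect_equal(pm$labels[roi[k], , ], (probs[[k]] >= 0.5) * 1L,
                 ignore_attr = TRUE)
  }
})

test_that("residual skips do not hurt early training (ablation contrast)", {
  phantoms <- generate_phantom_cohort(n_subjects = 4, size = 32,
                                      n_slices = 4, n_notch_slices = 3,
                                      seed = 3)
  samples <- prepare_training_samples(phantoms, 32)
  wins <- 0L
  for (seed in 1:5) {
    final_loss <- vapply(c(TRUE, FALSE), function(res) {
      set.seed(seed)
      m <- build_network(network_spec(base_channels = 2, input_size = 32,
                                      residual = res))
      fit <- train_network(m, samples,
                           training_config(epochs = 10, seed = seed))
      tail(fit$history$train_loss, 1)
    }, numeric(1))
    if (final_loss[1] <= final_loss[2]) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
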