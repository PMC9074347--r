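# Shared fixtures, all generated in code.  Heavier objects are cached per
# test run so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_geometry <- function(n_slices = 3L, size = 16L, spacing = 1) {
  voxel_geometry(spacing, spacing, 4.0, 0.4, n_rows = size, n_cols = size,
                 n_slices = n_slices)
}

random_binary_mask <- function(size = 12L, p = 0.3) {
  matrix(as.numeric(runif(size * size) < p), size, size)
}

# A clean low-noise phantom used across io/preprocess/train tests.
easy_phantom <- function() {
  cached("easy_phantom", generate_phantom(
    phantom_spec(size = 32, noise_sd = 0.02, bias_amplitude = 0.1),
    subject_id = "easy"
  ))
}

# Tiny trained model on one easy slice (reused by prediction tests).
tiny_model <- function() {
  cached("tiny_model", {
    samples <- prepare_training_samples(list(easy = easy_phantom()), 32)
    set.seed(3)
    model <- build_network(network_spec(base_channels = 4, input_size = 32))
    fit <- train_network(model, samples,
                         training_config(learning_rate = 0.01, epochs = 5,
                                         seed = 3))
    fit$model
  })
}
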