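#' Training hyperparameters
#'
#' Defaults follow the study protocol: stochastic gradient descent with
#' momentum, learning rate 1e-4, dice loss, 50 epochs, five folds.  Batch
#' size 8 and momentum 0.9 are conventional choices.  The seed controls
#' batch shuffling and the augmentation stream.
#'
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param epochs Number of training epochs (default 50).
#' @param batch_size Slices per optimization step (default 8).
#' @param n_folds Folds for cross-validation (default 5).
#' @param binarize_threshold Probability cut for mask binarization
#'   (default 0.5).
#' @param augmentation Optional [augmentation_spec()] applied on the fly to
#'   every training slice each epoch; `NULL` disables augmentation.
#' @param seed Integer seed.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-4, momentum = 0.9,
                            epochs = 50L, batch_size = 8L, n_folds = 5L,
                            binarize_threshold = 0.5, augmentation = NULL,
                            seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 0,
            batch_size >= 1, n_folds >= 2,
            binarize_threshold > 0, binarize_threshold < 1)
  if (!is.null(augmentation)) {
    stopifnot(inherits(augmentation, "augmentation_spec"))
  }
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         n_folds = as.integer(n_folds),
         binarize_threshold = binarize_threshold,
         augmentation = augmentation, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Soft dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` over the whole pair.
#' On binary predictions this equals `1 - dsc()` up to the epsilon
#' regularizer.  Values lie in `[0, 1]`.
#'
#' @param pred_probs Array of predicted probabilities in `[0, 1]`.
#' @param truth_mask Binary array of the same shape.
#' @param eps Regularizer guarding empty masks (default 1e-6).
#' @return Scalar loss.
#' @examples
#' t <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(t, t)                 # ~0
#' dice_loss(matrix(0.5, 2, 2), t) # 0.5
#' @export
dice_loss <- function(pred_probs, truth_mask, eps = 1e-6) {
  if (!all(dim2(pred_probs) == dim2(truth_mask))) {
    stop("prediction and truth shapes differ")
  }
  s <- sum(pred_probs * truth_mask)
  d <- sum(pred_probs) + sum(truth_mask)
  1 - (2 * s + eps) / (d + eps)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Mean per-sample soft dice loss over a (1,H,W,N) batch and its gradient
# with respect to the predictions.
dice_loss_batch <- function(pred, truth, eps = 1e-6) {
  d <- dim(pred)
  n <- d[4]
  m <- prod(d[1:3])
  pm <- matrix(pred, m, n)
  tm <- matrix(truth, m, n)
  s <- colSums(pm * tm)
  den <- colSums(pm) + colSums(tm)
  loss_i <- 1 - (2 * s + eps) / (den + eps)
  # d/dp_i of loss for each sample: -(2 t_i (den+eps) - (2 s+eps)) / (den+eps)^2
  grad <- -(2 * tm * rep(den + eps, each = m) -
              rep(2 * s + eps, each = m)) / rep((den + eps)^2, each = m)
  grad <- grad / n
  dim(grad) <- d
  list(loss = mean(loss_i), grad = grad, per_sample = loss_i)
}

samples_to_batch <- function(samples) {
  h <- nrow(samples[[1]]$image_2d)
  w <- ncol(samples[[1]]$image_2d)
  n <- length(samples)
  x <- array(0, c(1, h, w, n))
  t <- array(0, c(1, h, w, n))
  for (i in seq_len(n)) {
    x[1, , , i] <- samples[[i]]$image_2d
    t[1, , , i] <- samples[[i]]$mask_2d
  }
  list(x = x, t = t)
}

#' Train the segmentation network
#'
#' SGD + momentum on the (mean per-slice) soft dice loss.  Training slices
#' are shuffled every epoch; augmentation, when configured, is applied on
#' the fly so every epoch sees a fresh random transform of each slice.
#' All randomness flows from `config$seed`, so a fixed seed reproduces the
#' training trajectory on the same numeric backend.  Parameters are updated
#' in place; the model is also returned for chaining.
#'
#' @param model A `notch_model` from [build_network()].
#' @param samples List of [slice_sample()] training slices.
#' @param config A [training_config()].
#' @param val_samples Optional list of validation slices; if given, the
#'   mean per-slice Dice similarity on them is recorded each epoch.
#' @param verbose Print one line per epoch.
#' @return A list with `model` and `history` (a tibble with one row per
#'   epoch: `epoch`, `train_loss`, `val_dsc`).
#' @export
train_network <- function(model, samples, config, val_samples = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "notch_model"),
            inherits(config, "training_config"), length(samples) >= 1)
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_dsc = numeric())
  if (config$epochs == 0) return(list(model = model, history = history))
  state <- new.env(parent = emptyenv())
  with_preserved_rng(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(samples))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        bs <- samples[idx]
        if (!is.null(config$augmentation)) {
          bs <- lapply(bs, augment, spec = config$augmentation)
        }
        batch <- samples_to_batch(bs)
        fwd <- network_forward(model, batch$x, training = TRUE)
        dl <- dice_loss_batch(fwd$output, batch$t)
        if (!is.finite(dl$loss)) {
          stop(sprintf("training diverged (non-finite loss at epoch %d)",
                       epoch))
        }
        losses <- c(losses, dl$loss)
        bwd <- network_backward(model, fwd, dl$grad)
        sgd_step(model, bwd$grads, state, config$learning_rate,
                 config$momentum)
      }
      vd <- if (!is.null(val_samples)) {
        mean_slice_dsc(model, val_samples, config)
      } else NA_real_
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_dsc = vd
      ))
      if (verbose) {
        message(sprintf("epoch %d: train dice loss %.4f%s", epoch,
                        mean(losses),
                        if (is.na(vd)) "" else sprintf(", val DSC %.4f", vd)))
      }
    }
  })
  recalibrate_bn(model, samples, config$batch_size)
  model$trained_epochs <- model$trained_epochs + config$epochs
  list(model = model, history = history)
}

# Recompute batch-norm running statistics exactly, by averaging the batch
# statistics over one pass of the training set with the final weights
# ("precise BN").  The EMA collected during training lags behind the
# weights; replacing it removes the train/inference prediction gap.
recalibrate_bn <- function(model, samples, batch_size = 8L) {
  bn_ids <- which(vapply(model$nodes, function(nd) nd$op == "bn",
                         logical(1)))
  if (length(bn_ids) == 0) return(invisible(model))
  sums <- list()
  nb <- 0L
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(samples))
    batch <- samples_to_batch(samples[idx])
    fwd <- network_forward(model, batch$x, training = TRUE)
    nb <- nb + 1L
    for (id in bn_ids) {
      x <- fwd$vals[[model$nodes[[id]]$inputs[1]]]
      xm <- matrix(x, nrow = dim(x)[1])
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu^2
      key <- as.character(id)
      if (is.null(sums[[key]])) {
        sums[[key]] <- list(mu = mu, v = v)
      } else {
        sums[[key]]$mu <- sums[[key]]$mu + mu
        sums[[key]]$v <- sums[[key]]$v + v
      }
    }
  }
  for (id in bn_ids) {
    p <- model$nodes[[id]]$params
    key <- as.character(id)
    p$rmean <- sums[[key]]$mu / nb
    p$rvar <- pmax(sums[[key]]$v / nb, 0)
  }
  invisible(model)
}

# Mean per-slice DSC of thresholded predictions on a sample list.
mean_slice_dsc <- function(model, samples, config) {
  probs <- predict_slices(model, samples, config$batch_size)
  ds <- vapply(seq_along(samples), function(i) {
    dsc_arrays((probs[[i]] >= config$binarize_threshold) * 1,
               samples[[i]]$mask_2d)
  }, numeric(1))
  mean(ds)
}

# Forward a list of slice samples in batches; returns per-slice probability
# matrices (inference mode: batch-norm running statistics).
predict_slices <- function(model, samples, batch_size = 8L) {
  out <- vector("list", length(samples))
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(samples))
    batch <- samples_to_batch(samples[idx])
    fwd <- network_forward(model, batch$x, training = FALSE)
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- matrix(fwd$output[1, , , k],
                              dim(fwd$output)[2], dim(fwd$output)[3])
    }
  }
  out
}

#' Subject-level cross-validation folds
#'
#' Randomly partitions subjects into `n_folds` disjoint validation folds of
#' near-equal size; every subject is validated exactly once.
#'
#' @param subject_ids Character vector of (unique) subject ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed making the assignment deterministic.
#' @return A list of character vectors, one per fold, whose union is
#'   `subject_ids`.
#' @export
cv_folds <- function(subject_ids, n_folds = 5L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < n_folds) {
    stop("need at least as many subjects as folds")
  }
  with_preserved_rng(seed, {
    ord <- sample(subject_ids)
  })
  fold_of <- rep_len(seq_len(n_folds), length(ord))
  lapply(seq_len(n_folds), function(f) sort(ord[fold_of == f]))
}

#' Cross-validate the segmentation network
#'
#' Subject-level k-fold cross-validation: subjects are partitioned into
#' disjoint folds; for each fold a fresh network is trained on the other
#' folds' slices and evaluated on the held-out subjects (per-subject Dice
#' similarity over the stacked ROI slices, then averaged).  No subject's
#' slices ever appear in both the training and validation side of a fold.
#'
#' @param samples List of [slice_sample()] objects (grouped by their
#'   `subject_id` fields).
#' @param config A [training_config()]; `config$n_folds` folds are used.
#' @param net_spec A [network_spec()] for the per-fold models.
#' @return A list with `per_subject` (tibble: fold, subject_id, dsc),
#'   `per_fold` (tibble: fold, mean_dsc), and `summary` (mean and SD of the
#'   per-subject DSC).
#' @export
crossvalidate <- function(samples, config, net_spec) {
  stopifnot(inherits(config, "training_config"),
            inherits(net_spec, "network_spec"))
  ids <- vapply(samples, function(s) s$subject_id, character(1))
  folds <- cv_folds(unique(ids), config$n_folds, config$seed)
  rows <- list()
  for (f in seq_along(folds)) {
    val_ids <- folds[[f]]
    train_samples <- samples[!ids %in% val_ids]
    with_preserved_rng(config$seed + f, {
      model <- build_network(net_spec)
    })
    fit <- train_network(model, train_samples, config)
    for (sid in val_ids) {
      subj <- samples[ids == sid]
      d <- subject_stack_dsc(fit$model, subj, config)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fold = f, subject_id = sid, dsc = d
      )
    }
  }
  per_subject <- dplyr::bind_rows(rows)
  per_fold <- dplyr::summarise(dplyr::group_by(per_subject, .data$fold),
                               mean_dsc = mean(.data$dsc), .groups = "drop")
  list(
    per_subject = per_subject,
    per_fold = per_fold,
    summary = tibble::tibble(mean_dsc = mean(per_subject$dsc),
                             sd_dsc = sd(per_subject$dsc))
  )
}

# 3D DSC of one subject: predictions on the subject's slices stacked
# against the stacked truth.
subject_stack_dsc <- function(model, subj_samples, config) {
  probs <- predict_slices(model, subj_samples, config$batch_size)
  pred <- vapply(probs, function(p) (p >= config$binarize_threshold) * 1,
                 matrix(0, nrow(probs[[1]]), ncol(probs[[1]])))
  truth <- vapply(subj_samples, function(s) s$mask_2d + 0,
                  matrix(0, nrow(probs[[1]]), ncol(probs[[1]])))
  dsc_arrays(pred, truth)
}

#' Predict a 3D segmentation mask for a volume
#'
#' Runs the trained network slice by slice (inference mode), thresholds the
#' probability maps at `threshold`, resamples them back to the native grid
#' (nearest neighbour) and stacks them into a mask carrying the input
#' volume's geometry.  Slices are rescaled to `[0, 1]` and resized to the
#' network input size before the forward pass.
#'
#' @param model A trained `notch_model`.
#' @param volume An [image_volume()].
#' @param threshold Binarization threshold (default 0.5).
#' @param batch_size Slices per forward pass.
#' @return A [segmentation_mask()] aligned with `volume`.
#' @export
predict_mask <- function(model, volume, threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(model, "notch_model"),
            inherits(volume, "image_volume"))
  g <- volume$geometry
  size <- model$spec$input_size
  samples <- lapply(seq_len(g$n_slices), function(z) {
    img <- volume$voxels[z, , ]
    if (diff(range(img)) > 0) img <- rescale_unit(img)
    resize_to(slice_sample(img, img * 0, volume$subject_id, z), size)
  })
  probs <- predict_slices(model, samples, batch_size)
  lab <- array(0L, dim = c(g$n_slices, g$n_rows, g$n_cols))
  for (z in seq_len(g$n_slices)) {
    m <- (probs[[z]] >= threshold) * 1
    if (!all(dim(m) == c(g$n_rows, g$n_cols))) {
      m <- resize_matrix(m, g$n_rows, g$n_cols, "nearest")
    }
    lab[z, , ] <- (m > 0.5) * 1L
  }
  segmentation_mask(lab, g, volume$subject_id)
}

#' Build per-slice training samples from phantom subjects
#'
#' Extracts the ROI-bearing slices of each phantom subject, rescales the
#' intensities of every slice to `[0, 1]`, optionally matches each slice's
#' histogram to a reference slice, and resizes to the network input size.
#'
#' @param phantoms Named list of `generate_phantom()` results (or any list
#'   of lists with `volume` and `mask`).
#' @param input_size Network input size.
#' @param match_histograms Match every slice to the reference slice (the
#'   first ROI slice of the lexicographically first subject).
#' @return A list of [slice_sample()] objects across all subjects.
#' @export
prepare_training_samples <- function(phantoms, input_size,
                                     match_histograms = FALSE) {
  ids <- names(phantoms)
  if (is.null(ids)) ids <- as.character(seq_along(phantoms))
  samples <- list()
  for (i in order(ids)) {
    ph <- phantoms[[i]]
    sl <- extract_roi_slices(ph$volume, ph$mask)
    samples <- c(samples, sl)
  }
  reference <- if (match_histograms && length(samples) > 0) {
    samples[[1]]$image_2d
  } else NULL
  lapply(samples, function(s) {
    img <- s$image_2d
    if (!is.null(reference)) img <- histogram_match(img, reference)
    img <- rescale_unit(img)
    resize_to(slice_sample(img, s$mask_2d, s$subject_id, s$slice_index),
              input_size)
  })
}

#' Held-out evaluation of a trained model on phantom subjects
#'
#' For each subject, computes the Dice similarity of the thresholded
#' predictions over the subject's ROI slice stack (the 3D DSC convention
#' used throughout), plus the predicted notch volume from a full-stack
#' prediction and the relative volume error against the analytic truth.
#'
#' @param model A trained `notch_model`.
#' @param phantoms Named list of `generate_phantom()` results.
#' @param config A [training_config()] (threshold and batch size).
#' @return A tibble: `subject_id`, `dsc`, `true_volume_cm3`,
#'   `pred_volume_cm3`, `relative_error`.
#' @export
evaluate_segmentation <- function(model, phantoms, config = training_config()) {
  ids <- names(phantoms)
  if (is.null(ids)) ids <- as.character(seq_along(phantoms))
  rows <- purrr::map2(phantoms, ids, function(ph, id) {
    samples <- prepare_training_samples(stats::setNames(list(ph), id),
                                        model$spec$input_size)
    d <- subject_stack_dsc(model, samples, config)
    pm <- predict_mask(model, ph$volume, config$binarize_threshold,
                       config$batch_size)
    pv <- notch_volume(pm)$volume_cm3
    tv <- if (!is.null(ph$true_volume_cm3)) ph$true_volume_cm3 else
      notch_volume(ph$mask)$volume_cm3
    tibble::tibble(
      subject_id = id, dsc = d, true_volume_cm3 = tv, pred_volume_cm3 = pv,
      relative_error = (tv - pv) / tv
    )
  })
  dplyr::bind_rows(rows)
}
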