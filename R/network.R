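#' Residual U-Net architecture specification
#'
#' Fixed architecture counts of the segmentation network: 10 standalone
#' convolutional layers, 11 residual blocks, 2 pyramid-pooling modules,
#' 5 upsampling layers and 6 combine blocks, plus a per-pixel 1x1
#' convolution head ("FC" layer) and a sigmoid.  The encoder has `depth`
#' resolution levels of residual blocks with 2x2 max-pool downsampling;
#' pyramid pooling sits at the bottleneck and before the head; each decoder
#' stage is nearest-neighbour upsampling followed by a combine block
#' (encoder skip fusion) and a convolution.  Channel widths start at
#' `base_channels` and double per level, capped at 512.
#'
#' @param base_channels Channel width of the first level (default 32; the
#'   reduced desk-scale configuration uses 8).
#' @param input_size Square input size in pixels; must be divisible by
#'   `2^depth` (default 512).
#' @param depth Number of encoder resolution levels (default 5).
#' @param psp_bins Pyramid pooling grid sizes (default 1, 2, 4, 8; bins
#'   larger than the feature map are dropped at that placement).
#' @param residual Keep the residual skip paths (`FALSE` gives the plain
#'   U-Net ablation in which blocks are conv-BN-ReLU stacks without the
#'   identity shortcut).
#' @param init_gain Multiplier on the He initialization scale of every
#'   convolution except the head.  Because each convolution is followed by
#'   batch normalization, its output is invariant to the weight scale and
#'   the gain instead sets the effective SGD step size (proportional to
#'   `learning_rate / ||W||^2`); the default makes the network train
#'   within few epochs at the protocol's learning rate of 1e-4.
#' @param head_prior Expected foreground fraction of a slice; the head
#'   bias is initialized to its logit so that initial predictions match
#'   the class prior instead of 0.5 (the usual remedy for extreme
#'   foreground/background imbalance under dice-type losses).
#' @param n_conv_layers,n_residual_blocks,n_psp_modules,n_upsampling,n_combine_blocks
#'   Architecture counts; the builder verifies the constructed graph
#'   against them.
#' @return A `network_spec` object.
#' @export
network_spec <- function(base_channels = 32L, input_size = 512L, depth = 5L,
                         psp_bins = c(1L, 2L, 4L, 8L), residual = TRUE,
                         init_gain = 0.02, head_prior = 0.02,
                         n_conv_layers = 10L,
                         n_residual_blocks = 11L, n_psp_modules = 2L,
                         n_upsampling = 5L, n_combine_blocks = 6L) {
  stopifnot(base_channels >= 1, depth >= 1, length(psp_bins) >= 1,
            init_gain > 0, head_prior > 0, head_prior < 1)
  if (input_size %% 2^depth != 0) {
    stop("input_size must be divisible by 2^depth")
  }
  structure(
    list(base_channels = as.integer(base_channels),
         input_size = as.integer(input_size), depth = as.integer(depth),
         psp_bins = as.integer(psp_bins), residual = isTRUE(residual),
         init_gain = init_gain, head_prior = head_prior,
         n_conv_layers = as.integer(n_conv_layers),
         n_residual_blocks = as.integer(n_residual_blocks),
         n_psp_modules = as.integer(n_psp_modules),
         n_upsampling = as.integer(n_upsampling),
         n_combine_blocks = as.integer(n_combine_blocks)),
    class = "network_spec"
  )
}

level_channels <- function(base, level, cap = 512L) {
  as.integer(min(base * 2^(level - 1), cap))
}

# Convolution immediately followed by batch normalization: with BN the
# layer output is invariant to the weight scale, so the init gain sets the
# effective SGD step size at a fixed learning rate (effective step ~
# lr / ||W||^2); every convolution except the sigmoid head uses this pair.
conv_bn <- function(b, input, cout, k, tag, blk, gain) {
  h <- nd_conv(b, input, cout, k, tag, blk, weight_scale = gain)
  nd_bn(b, h, tag, blk)
}

# Residual block: two conv3x3-BN-ReLU stages on the function path,
# identity skip (1x1 projection + BN when the channel count changes),
# elementwise sum.  With residual = FALSE the skip is dropped (ablation).
rb_build <- function(b, input, cout, residual = TRUE, gain = 1) {
  blk <- new_block(b)
  cin <- node_channels(b, input)
  h <- conv_bn(b, input, cout, 3L, "rb", blk, gain)
  h <- nd_relu(b, h, "rb", blk)
  h <- conv_bn(b, h, cout, 3L, "rb", blk, gain)
  h <- nd_relu(b, h, "rb", blk)
  if (!residual) return(h)
  skip <- if (cin == cout) input else {
    conv_bn(b, input, cout, 1L, "rb", blk, gain)
  }
  nd_add(b, h, skip, "rb", blk)
}

# Combine block: channel concatenation of decoder and encoder features,
# ReLU, 3x3 convolution (+BN) to the target width.
combine_build <- function(b, dec, enc, cout, gain = 1) {
  blk <- new_block(b)
  h <- nd_concat(b, c(dec, enc), "combine", blk)
  h <- nd_relu(b, h, "combine", blk)
  conv_bn(b, h, cout, 3L, "combine", blk, gain)
}

# Pyramid pooling: per bin size, grid max-pool -> 1x1 conv -> upsample to
# the input size; concatenate with the input and fuse with a 1x1 conv.
psp_build <- function(b, input, bins, gain = 1) {
  blk <- new_block(b)
  c <- node_channels(b, input)
  spatial <- node_spatial(b, input)
  bins <- bins[bins <= spatial]
  if (length(bins) == 0) stop("pyramid pooling needs at least one bin size")
  cb <- max(c %/% length(bins), 1L)
  branches <- integer(length(bins))
  for (k in seq_along(bins)) {
    h <- nd_adaptpool(b, input, bins[k], "psp", blk)
    h <- conv_bn(b, h, cb, 1L, "psp", blk, gain)
    branches[k] <- nd_upsample(b, h, like = input, "psp", blk)
  }
  h <- nd_concat(b, c(input, branches), "psp", blk)
  conv_bn(b, h, c, 1L, "psp", blk, gain)
}

#' Build the residual U-Net segmentation model
#'
#' Constructs the full network graph with randomly initialized weights
#' (He initialization, drawn from the current RNG stream — seed it for
#' reproducible initialization).  The output is a per-pixel foreground
#' probability map at input resolution.
#'
#' @param spec A [network_spec()].
#' @return A `notch_model` object.
#' @examples
#' set.seed(1)
#' model <- build_network(network_spec(base_channels = 1, input_size = 32))
#' network_census(model)
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  b <- graph_builder()
  input <- nd_input(b, channels = 1L, spatial = spec$input_size)
  ch <- function(l) level_channels(spec$base_channels, l)

  enc <- integer(spec$depth)
  stem <- NA_integer_
  cur <- input
  for (l in seq_len(spec$depth)) {
    if (l > 1) cur <- nd_maxpool(b, cur)
    blk <- new_block(b)  # standalone level-entry convolution
    cur <- conv_bn(b, cur, ch(l), 3L, "conv", blk, spec$init_gain)
    cur <- nd_relu(b, cur, "conv", blk)
    if (l == 1) stem <- cur
    cur <- rb_build(b, cur, ch(l), spec$residual, spec$init_gain)
    cur <- rb_build(b, cur, ch(l), spec$residual, spec$init_gain)
    enc[l] <- cur
  }

  # bottleneck: pool once more, pyramid pooling, residual block
  cur <- nd_maxpool(b, cur)
  cur <- psp_build(b, cur, spec$psp_bins, spec$init_gain)
  cur <- rb_build(b, cur, ch(spec$depth), spec$residual, spec$init_gain)

  for (l in rev(seq_len(spec$depth))) {
    blk_up <- new_block(b)
    cur <- nd_upsample(b, cur, like = enc[l], "upsample", blk_up)
    cur <- combine_build(b, cur, enc[l], ch(l), spec$init_gain)
    blk <- new_block(b)  # standalone decoder convolution
    cur <- conv_bn(b, cur, ch(l), 3L, "conv", blk, spec$init_gain)
    cur <- nd_relu(b, cur, "conv", blk)
  }

  cur <- psp_build(b, cur, spec$psp_bins, spec$init_gain)
  cur <- combine_build(b, cur, stem, ch(1), spec$init_gain)
  head_blk <- new_block(b)
  cur <- nd_conv(b, cur, 1L, 1L, "head", head_blk)
  # class-prior bias initialization: the notch occupies a small fraction of
  # each slice, so the head starts predicting that prior rather than 0.5
  b$nodes[[cur]]$params$b[] <- stats::qlogis(spec$head_prior)
  nd_sigmoid(b, cur, "head", head_blk)

  model <- structure(
    list(nodes = b$nodes, spec = spec, trained_epochs = 0L),
    class = "notch_model"
  )
  census <- network_census(model)
  expected <- c(conv = spec$n_conv_layers, rb = spec$n_residual_blocks,
                psp = spec$n_psp_modules, upsample = spec$n_upsampling,
                combine = spec$n_combine_blocks)
  if (!identical(census[names(expected)], expected)) {
    stop(sprintf(
      "built graph census (%s) does not match the spec counts (%s)",
      paste(census[names(expected)], collapse = "/"),
      paste(expected, collapse = "/")
    ))
  }
  model
}

#' Census of architecture blocks in a built model
#'
#' Counts the distinct blocks of each kind in the constructed graph.
#'
#' @param model A `notch_model` from [build_network()].
#' @return Named integer vector with entries `conv`, `rb`, `psp`,
#'   `upsample`, `combine`.
#' @export
network_census <- function(model) {
  types <- vapply(model$nodes, function(nd) nd$block_type, character(1))
  ids <- vapply(model$nodes, function(nd) nd$block_id, integer(1))
  out <- vapply(c("conv", "rb", "psp", "upsample", "combine"),
                function(t) length(unique(ids[types == t & ids > 0])),
                integer(1))
  out
}

#' @export
print.notch_model <- function(x, ...) {
  cen <- network_census(x)
  cat(sprintf(
    paste0("<notch_model> base %d channels, input %d, depth %d",
           " (%d conv / %d RB / %d PSP / %d upsample / %d combine)",
           ", trained %d epochs\n"),
    x$spec$base_channels, x$spec$input_size, x$spec$depth,
    cen["conv"], cen["rb"], cen["psp"], cen["upsample"], cen["combine"],
    x$trained_epochs
  ))
  invisible(x)
}

# Wrap a feature map (C,H,W) or (C,H,W,N) as a 4D tensor.
as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3, 4)) {
    stop("feature map must be a 3D (C,H,W) or 4D (C,H,W,N) array")
  }
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

# Build a one-block scratch model around `builder_fn` and run it forward.
run_block <- function(x, builder_fn, training = TRUE) {
  x <- as_tensor4(x)
  b <- graph_builder()
  input <- nd_input(b, channels = dim(x)[1], spatial = dim(x)[2])
  builder_fn(b, input)
  model <- structure(list(nodes = b$nodes), class = "notch_model")
  fwd <- network_forward(model, x, training = training)
  y <- fwd$output
  attr(y, "model") <- model
  attr(y, "forward") <- fwd
  y
}

#' Apply a single residual block to a feature map
#'
#' Standalone functional form of the network's residual unit
#' (BN-ReLU-conv3x3 twice plus an identity or 1x1-projection skip), with
#' freshly initialized weights drawn from the current RNG stream; with
#' `weights = "zero"` the convolution weights are zero so the block reduces
#' to its skip path (output equals input when channel counts match).
#'
#' @param x Feature map, `(C, H, W)` or `(C, H, W, N)` array.
#' @param channels Output channel count.
#' @param weights `"random"` (He initialization) or `"zero"`.
#' @return The output feature map (same spatial size); the underlying
#'   one-block model is attached as attribute `"model"`.
#' @export
residual_block <- function(x, channels, weights = c("random", "zero")) {
  weights <- match.arg(weights)
  x <- as_tensor4(x)
  if (dim(x)[2] < 3 || dim(x)[3] < 3) stop("spatial dims must be >= 3")
  y <- run_block(x, function(b, input) {
    out <- rb_build(b, input, as.integer(channels))
    if (weights == "zero") {
      for (nd in b$nodes) {
        if (nd$op == "conv") {
          nd$params$W[] <- 0
          nd$params$b[] <- 0
        }
      }
      if (dim(x)[1] != channels) {
        stop("zero-weight residual block needs matching channel counts")
      }
    }
    out
  })
  y
}

#' Apply a combine block (skip-connection fusion)
#'
#' Concatenates decoder and encoder feature maps along channels, applies
#' ReLU and a 3x3 convolution to `channels` output channels.
#'
#' @param decoder,encoder Feature maps with equal spatial dims.
#' @param channels Output channel count.
#' @return The fused feature map with attribute `"model"`.
#' @export
combine_block <- function(decoder, encoder, channels) {
  decoder <- as_tensor4(decoder)
  encoder <- as_tensor4(encoder)
  if (!all(dim(decoder)[2:4] == dim(encoder)[2:4])) {
    stop("decoder and encoder feature maps must have equal spatial dims")
  }
  b <- graph_builder()
  i1 <- nd_input(b, dim(decoder)[1], dim(decoder)[2])
  i2 <- add_node(b, "input", channels = dim(encoder)[1],
                 spatial = dim(encoder)[2])
  combine_build(b, i1, i2, as.integer(channels))
  model <- structure(list(nodes = b$nodes), class = "notch_model")
  # two-input forward: seed both input nodes
  nodes <- model$nodes
  vals <- vector("list", length(nodes))
  vals[[i1]] <- decoder
  vals[[i2]] <- encoder
  fwd <- network_forward_seeded(model, vals, training = TRUE)
  y <- fwd$output
  attr(y, "model") <- model
  y
}

# forward pass with pre-seeded input values (for multi-input scratch blocks)
network_forward_seeded <- function(model, vals, training = FALSE) {
  nodes <- model$nodes
  caches <- vector("list", length(nodes))
  for (nd in nodes) {
    if (nd$op == "input") next
    r <- forward_one(nd, vals, training)
    vals[[nd$id]] <- r$y
    caches[[nd$id]] <- r$cache
  }
  list(vals = vals, caches = caches, output = vals[[length(nodes)]])
}

#' Apply a pyramid pooling module
#'
#' For each bin size: grid max-pool, 1x1 convolution, upsample back to the
#' input size; the branches are concatenated with the input and fused with
#' a final 1x1 convolution back to the input channel count.
#'
#' @param x Feature map, `(C, H, W)` or `(C, H, W, N)`.
#' @param bin_sizes Integer vector of pooling grid sizes.
#' @return The output feature map (same shape) with attribute `"model"`.
#' @export
psp_pooling <- function(x, bin_sizes = c(1L, 2L, 4L, 8L)) {
  if (length(bin_sizes) == 0) stop("bin_sizes must be non-empty")
  run_block(x, function(b, input) psp_build(b, input, as.integer(bin_sizes)))
}
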