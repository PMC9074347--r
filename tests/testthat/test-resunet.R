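test_that("built graph honours the architecture block census", {
  set.seed(1)
  model <- build_network(network_spec(base_channels = 1, input_size = 32))
  expect_equal(network_census(model),
               c(conv = 10L, rb = 11L, psp = 2L, upsample = 5L,
                 combine = 6L))
  expect_error(network_spec(input_size = 100), "divisible")
})

test_that("forward pass maps any valid input to a probability map", {
  set.seed(2)
  model <- build_network(network_spec(base_channels = 1, input_size = 64))
  x <- array(runif(64 * 64 * 2), c(1, 64, 64, 2))
  out <- notchseg:::network_forward(model, x, training = TRUE)$output
  expect_equal(dim(out), c(1L, 64L, 64L, 2L))
  expect_true(all(out > 0 & out < 1))
  # fully convolutional: doubling the input size doubles the output size
  x2 <- array(runif(128 * 128), c(1, 128, 128, 1))
  out2 <- notchseg:::network_forward(model, x2, training = TRUE)$output
  expect_equal(dim(out2)[2:3], c(128L, 128L))
})

test_that("residual block reduces to the identity with zero weights", {
  set.seed(3)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  y <- residual_block(x, channels = 4, weights = "zero")
  expect_equal(as.vector(y), as.vector(x))
  # output shape preserved for random weights too
  y2 <- residual_block(x, channels = 4)
  expect_equal(dim(y2), c(4L, 8L, 8L, 1L))
  expect_error(residual_block(array(0, c(2, 2, 2)), 2), "spatial")
})

test_that("gradient flows to the input through the residual skip", {
  set.seed(4)
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6, 1))
  y <- residual_block(x, channels = 2)
  model <- attr(y, "model")
  fwd <- attr(y, "forward")
  dy <- array(rnorm(length(fwd$output)), dim(fwd$output))
  bwd <- notchseg:::network_backward(model, fwd, dy)
  expect_true(all(is.finite(bwd$dinput)))
  expect_gt(sum(abs(bwd$dinput)), 0)
  # finite-difference check of the input gradient
  loss <- function(xx) {
    sum(notchseg:::network_forward(model, xx, training = TRUE)$output * dy)
  }
  eps <- 1e-6
  set.seed(5)
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (loss(xp) - loss(xm)) / (2 * eps)
    expect_equal(bwd$dinput[i], fd, tolerance = 1e-4)
  }
  # even when the function path is saturated (all-negative pre-activations
  # give zero ReLU gradient), the skip path still carries gradient
  yz <- residual_block(x, channels = 2, weights = "zero")
  mz <- attr(yz, "model")
  fz <- attr(yz, "forward")
  bz <- notchseg:::network_backward(mz, fz, dy)
  expect_equal(bz$dinput, dy)  # pure identity path
})

test_that("combine block fuses two inputs into the configured width", {
  set.seed(6)
  dec <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  enc <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  out <- combine_block(dec, enc, channels = 4)
  expect_equal(dim(out), c(4L, 8L, 8L, 1L))
  # output width independent of how channels split across the two inputs
  out2 <- combine_block(array(rnorm(6 * 8 * 8), c(6, 8, 8)),
                        array(rnorm(2 * 8 * 8), c(2, 8, 8)), channels = 4)
  expect_equal(dim(out2), dim(out))
  expect_error(combine_block(dec, array(0, c(5, 4, 4)), 4), "spatial")
})

test_that("pyramid pooling preserves shape and matches a pooling oracle", {
  set.seed(7)
  x <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  out <- psp_pooling(x, c(1, 2, 4, 8))
  expect_equal(dim(out), c(4L, 16L, 16L, 1L))
  # bin size 1 on a constant map stays spatially constant
  xc <- array(1, c(2, 8, 8))
  outc <- psp_pooling(xc, 1)
  for (ch in 1:2) {
    expect_lt(diff(range(outc[ch, , , 1])), 1e-12)
  }
  expect_error(psp_pooling(x, integer(0)), "non-empty")
  # grid max-pool branch equals brute-force per-bin maxima on an 8x8 map
  toy <- array(rnorm(8 * 8), c(1, 8, 8, 1))
  pooled <- notchseg:::.adaptpool_fwd(toy, 4L)$y
  m <- matrix(toy[1, , , 1], 8, 8)
  for (bi in 1:4) for (bj in 1:4) {
    expect_equal(pooled[1, bi, bj, 1],
                 max(m[(2 * bi - 1):(2 * bi), (2 * bj - 1):(2 * bj)]))
  }
})

test_that("dice loss matches its closed-form examples", {
  t <- matrix(0, 10, 10)
  t[3:7, 3:7] <- 1
  expect_lte(dice_loss(t, t), 1e-5)
  half <- matrix(c(1, 0), 10, 10)  # half foreground
  expect_equal(dice_loss(1 - half, half), 1, tolerance = 1e-5)
  # constant 0.5 prediction on half-foreground truth: loss = 0.5
  expect_equal(dice_loss(matrix(0.5, 10, 10), half), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("batch dice gradient agrees with finite differences", {
  set.seed(8)
  p <- array(runif(2 * 4 * 4 * 3, 0.05, 0.95), c(2, 4, 4, 3))
  t <- array(rbinom(length(p), 1, 0.3), dim(p))
  dl <- notchseg:::dice_loss_batch(p, t)
  eps <- 1e-7
  for (i in sample(length(p), 6)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (notchseg:::dice_loss_batch(pp, t)$loss -
             notchseg:::dice_loss_batch(pm, t)$loss) / (2 * eps)
    expect_equal(dl$grad[i], fd, tolerance = 1e-5)
  }
})
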