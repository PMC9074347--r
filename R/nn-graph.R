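# Minimal static-graph neural network engine.
#
# A model is an ordered list of nodes (a DAG in topological order).  Each
# node names an op, its input node ids, an optional parameter environment
# (environments so that SGD updates and batch-norm running statistics
# mutate in place), and a block tag used for the architecture census.
# Tensors are R arrays of dim (C, H, W, N); the heavy kernels (convolution,
# pooling, upsampling) are compiled (see src/ops.cpp).

graph_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b$n_blocks <- 0L
  b
}

new_block <- function(b) {
  b$n_blocks <- b$n_blocks + 1L
  b$n_blocks
}

add_node <- function(b, op, inputs = integer(), params = NULL,
                     cfg = list(), block_type = "aux", block_id = 0L,
                     channels = NA_integer_, spatial = NA_integer_) {
  id <- length(b$nodes) + 1L
  b$nodes[[id]] <- list(
    id = id, op = op, inputs = as.integer(inputs), params = params,
    cfg = cfg, block_type = block_type, block_id = block_id,
    channels = as.integer(channels), spatial = as.integer(spatial)
  )
  id
}

node_channels <- function(b, id) b$nodes[[id]]$channels
node_spatial <- function(b, id) b$nodes[[id]]$spatial

init_conv_params <- function(cin, cout, k, scale = 1) {
  p <- new.env(parent = emptyenv())
  fan_in <- cin * k * k
  p$W <- matrix(rnorm(cout * fan_in, sd = scale * sqrt(2 / fan_in)),
                cout, fan_in)
  p$b <- numeric(cout)
  p
}

init_bn_params <- function(c) {
  p <- new.env(parent = emptyenv())
  p$gamma <- rep(1, c)
  p$beta <- numeric(c)
  p$rmean <- numeric(c)
  p$rvar <- rep(1, c)
  p
}

nd_input <- function(b, channels, spatial) {
  add_node(b, "input", channels = channels, spatial = spatial)
}

nd_conv <- function(b, input, cout, k, block_type, block_id,
                    weight_scale = 1) {
  cin <- node_channels(b, input)
  add_node(b, "conv", input, params = init_conv_params(cin, cout, k,
                                                       weight_scale),
           cfg = list(k = k, pad = (k - 1L) %/% 2L),
           block_type = block_type, block_id = block_id,
           channels = cout, spatial = node_spatial(b, input))
}

nd_bn <- function(b, input, block_type, block_id) {
  c <- node_channels(b, input)
  add_node(b, "bn", input, params = init_bn_params(c),
           block_type = block_type, block_id = block_id,
           channels = c, spatial = node_spatial(b, input))
}

nd_relu <- function(b, input, block_type, block_id) {
  add_node(b, "relu", input, block_type = block_type, block_id = block_id,
           channels = node_channels(b, input),
           spatial = node_spatial(b, input))
}

nd_sigmoid <- function(b, input, block_type = "head", block_id = 0L) {
  add_node(b, "sigmoid", input, block_type = block_type,
           block_id = block_id, channels = node_channels(b, input),
           spatial = node_spatial(b, input))
}

nd_add <- function(b, in1, in2, block_type, block_id) {
  add_node(b, "add", c(in1, in2), block_type = block_type,
           block_id = block_id, channels = node_channels(b, in1),
           spatial = node_spatial(b, in1))
}

nd_concat <- function(b, inputs, block_type, block_id) {
  add_node(b, "concat", inputs, block_type = block_type,
           block_id = block_id,
           channels = sum(vapply(inputs, function(i) node_channels(b, i),
                                 integer(1))),
           spatial = node_spatial(b, inputs[1]))
}

nd_maxpool <- function(b, input, block_type = "aux", block_id = 0L) {
  add_node(b, "maxpool", input, block_type = block_type,
           block_id = block_id, channels = node_channels(b, input),
           spatial = node_spatial(b, input) %/% 2L)
}

nd_adaptpool <- function(b, input, bins, block_type, block_id) {
  add_node(b, "adaptpool", input, cfg = list(bins = as.integer(bins)),
           block_type = block_type, block_id = block_id,
           channels = node_channels(b, input), spatial = as.integer(bins))
}

# Upsample to the spatial size of node `like` (resolved dynamically at
# forward time, so the graph stays fully convolutional).
nd_upsample <- function(b, input, like, block_type, block_id) {
  add_node(b, "upsample", input, cfg = list(like = as.integer(like)),
           block_type = block_type, block_id = block_id,
           channels = node_channels(b, input),
           spatial = node_spatial(b, like))
}

# ---------------------------------------------------------------------------
# forward / backward

network_forward <- function(model, x, training = FALSE) {
  nodes <- model$nodes
  vals <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (nd in nodes) {
    if (nd$op == "input") {
      vals[[nd$id]] <- x
      next
    }
    r <- forward_one(nd, vals, training)
    vals[[nd$id]] <- r$y
    caches[[nd$id]] <- r$cache
  }
  list(vals = vals, caches = caches, output = vals[[length(nodes)]])
}

forward_one <- function(nd, vals, training) {
  xin <- vals[[nd$inputs[1]]]
  switch(nd$op,
    conv = list(y = .conv2d_fwd(xin, nd$params$W, nd$params$b, nd$cfg$k,
                                nd$cfg$pad), cache = NULL),
    bn = {
      r <- bn_forward(xin, nd$params, training)
      list(y = r$y, cache = r$cache)
    },
    relu = {
      y <- xin
      y[y < 0] <- 0
      list(y = y, cache = xin > 0)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-xin))
      list(y = y, cache = y)
    },
    add = list(y = xin + vals[[nd$inputs[2]]], cache = NULL),
    concat = {
      xs <- vals[nd$inputs]
      d <- dim(xs[[1]])
      cs <- vapply(xs, function(a) dim(a)[1], integer(1))
      y <- array(0, c(sum(cs), d[2], d[3], d[4]))
      off <- 0L
      for (a in xs) {
        y[off + seq_len(dim(a)[1]), , , ] <- a
        off <- off + dim(a)[1]
      }
      list(y = y, cache = cs)
    },
    maxpool = {
      r <- .maxpool2_fwd(xin)
      list(y = r$y, cache = list(idx = r$idx, in_dim = dim(xin)))
    },
    adaptpool = {
      r <- .adaptpool_fwd(xin, nd$cfg$bins)
      list(y = r$y, cache = list(idx = r$idx, in_dim = dim(xin)))
    },
    upsample = {
      ref <- dim(vals[[nd$cfg$like]])
      list(y = .upsample_fwd(xin, ref[2], ref[3]),
           cache = list(in_dim = dim(xin)))
    },
    stop(sprintf("unknown op '%s'", nd$op))
  )
}

network_backward <- function(model, fwd, dout) {
  nodes <- model$nodes
  vals <- fwd$vals
  caches <- fwd$caches
  douts <- vector("list", length(nodes))
  douts[[length(nodes)]] <- dout
  grads <- vector("list", length(nodes))
  acc <- function(id, d) {
    douts[[id]] <<- if (is.null(douts[[id]])) d else douts[[id]] + d
  }
  for (id in rev(seq_along(nodes))) {
    nd <- nodes[[id]]
    dy <- douts[[id]]
    if (is.null(dy) || nd$op == "input") next
    switch(nd$op,
      conv = {
        r <- .conv2d_bwd(vals[[nd$inputs[1]]], nd$params$W, dy,
                         nd$cfg$k, nd$cfg$pad)
        grads[[id]] <- list(W = r$dW, b = r$db)
        acc(nd$inputs[1], r$dx)
      },
      bn = {
        r <- bn_backward(dy, caches[[id]], nd$params)
        grads[[id]] <- r$grads
        acc(nd$inputs[1], r$dx)
      },
      relu = {
        d <- dy
        d[!caches[[id]]] <- 0
        acc(nd$inputs[1], d)
      },
      sigmoid = {
        y <- caches[[id]]
        acc(nd$inputs[1], dy * y * (1 - y))
      },
      add = {
        acc(nd$inputs[1], dy)
        acc(nd$inputs[2], dy)
      },
      concat = {
        cs <- caches[[id]]
        off <- 0L
        for (k in seq_along(nd$inputs)) {
          acc(nd$inputs[k], dy[off + seq_len(cs[k]), , , , drop = FALSE])
          off <- off + cs[k]
        }
      },
      maxpool = {
        cc <- caches[[id]]
        acc(nd$inputs[1], .maxpool2_bwd(dy, cc$idx, cc$in_dim))
      },
      adaptpool = {
        cc <- caches[[id]]
        acc(nd$inputs[1], .maxpool2_bwd(dy, cc$idx, cc$in_dim))
      },
      upsample = {
        acc(nd$inputs[1], .upsample_bwd(dy, caches[[id]]$in_dim))
      }
    )
    douts[[id]] <- NULL
  }
  list(grads = grads, dinput = douts[[1]])
}

bn_forward <- function(x, p, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu^2
    v[v < 0] <- 0
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- p$gamma * xhat + p$beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv = inv, training = training,
                           dims = d))
}

bn_backward <- function(dy, cache, p) {
  d <- cache$dims
  dym <- matrix(dy, nrow = d[1])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * p$gamma
  if (cache$training) {
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
      cache$inv
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
}

# SGD + momentum (velocity form v <- m v + g; p <- p - lr v), applied in
# place to the model's parameter environments.
sgd_step <- function(model, grads, state, lr, momentum) {
  for (id in seq_along(model$nodes)) {
    g <- grads[[id]]
    if (is.null(g)) next
    p <- model$nodes[[id]]$params
    for (nm in names(g)) {
      key <- sprintf("%d.%s", id, nm)
      v <- state[[key]]
      v <- if (is.null(v)) g[[nm]] else momentum * v + g[[nm]]
      state[[key]] <- v
      p[[nm]] <- p[[nm]] - lr * v
    }
  }
  invisible(NULL)
}

# Deep-copy a model (parameter environments are otherwise shared).
clone_model <- function(model) {
  model$nodes <- lapply(model$nodes, function(nd) {
    if (!is.null(nd$params)) {
      nd$params <- list2env(as.list(nd$params), parent = emptyenv())
    }
    nd
  })
  model
}
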