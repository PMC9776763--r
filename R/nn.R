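# Compact convolutional-network engine backing the detector and the
# weak/moderate/strong classifier.  Feature maps are numeric arrays
# dim c(H, W, C); convolutions are stride-1 "same"; all randomness
# (weight init, dropout, shuffling, augmentation) is drawn from R's RNG so a
# single set.seed() call makes training reproducible.

nn_conv <- function(out_channels, k = 3L) {
  list(type = "conv", k = as.integer(k), out = as.integer(out_channels))
}
nn_relu <- function() list(type = "relu")
nn_maxpool <- function() list(type = "maxpool")
nn_upsample <- function(factor = 2L) {
  list(type = "upsample", factor = as.integer(factor))
}
nn_dropout <- function(rate = 0.25) list(type = "dropout", rate = rate)
nn_flatten <- function() list(type = "flatten")
nn_dense <- function(units) list(type = "dense", units = as.integer(units))

# Initialise weights (He-scaled zero-mean Gaussians) for a layer spec list.
# Consumes the current RNG state; callers seed beforehand.
nn_init <- function(spec, input_shape) {
  shape <- input_shape # c(H, W, C) tracked through the stack
  layers <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    l <- spec[[i]]
    if (l$type == "conv") {
      fan_in <- l$k * l$k * shape[3]
      l$w <- matrix(stats::rnorm(fan_in * l$out, sd = sqrt(2 / fan_in)),
                    fan_in, l$out)
      l$b <- numeric(l$out)
      shape[3] <- l$out
    } else if (l$type == "maxpool") {
      shape[1:2] <- shape[1:2] %/% 2L
    } else if (l$type == "upsample") {
      shape[1:2] <- shape[1:2] * l$factor
    } else if (l$type == "flatten") {
      l$in_shape <- shape
      shape <- c(prod(shape), 1L, 1L)
    } else if (l$type == "dense") {
      fan_in <- shape[1]
      l$w <- matrix(stats::rnorm(fan_in * l$units, sd = sqrt(2 / fan_in)),
                    fan_in, l$units)
      l$b <- numeric(l$units)
      shape <- c(l$units, 1L, 1L)
    }
    layers[[i]] <- l
  }
  structure(list(layers = layers, input_shape = input_shape,
                 output_shape = shape), class = "erallred_net")
}

nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    cache <- NULL
    if (l$type == "conv") {
      cache <- list(x = x)
      x <- cpp_conv_forward(x, l$w, l$b, l$k)
    } else if (l$type == "relu") {
      cache <- list(mask = x > 0)
      x <- x * cache$mask
    } else if (l$type == "maxpool") {
      cache <- list(in_dim = dim(x))
      res <- cpp_maxpool_forward(x)
      cache$idx <- res$idx
      x <- res$out
    } else if (l$type == "upsample") {
      cache <- list(in_dim = dim(x))
      x <- cpp_upsample_forward(x, l$factor)
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
        cache <- list(mask = mask)
        x <- x * mask
      }
    } else if (l$type == "flatten") {
      x <- as.numeric(x)
    } else if (l$type == "dense") {
      cache <- list(x = x)
      x <- drop(crossprod(l$w, x)) + l$b
    }
    caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    if (l$type == "conv") {
      if (is.null(dim(dout))) dim(dout) <- c(dim(cache$x)[1:2], l$out)
      res <- cpp_conv_backward(cache$x, l$w, dout, l$k)
      grads[[i]] <- list(dw = res$dw, db = res$db)
      dout <- res$dx
    } else if (l$type == "relu") {
      dout <- dout * cache$mask
    } else if (l$type == "maxpool") {
      dout <- cpp_maxpool_backward(dout, cache$idx, cache$in_dim)
    } else if (l$type == "upsample") {
      dout <- cpp_upsample_backward(dout, l$factor, cache$in_dim)
    } else if (l$type == "dropout") {
      if (!is.null(cache)) dout <- dout * cache$mask
    } else if (l$type == "flatten") {
      # handled by the preceding conv reshaping dout
    } else if (l$type == "dense") {
      grads[[i]] <- list(dw = outer(cache$x, dout), db = dout)
      dout <- drop(l$w %*% dout)
    }
  }
  grads
}

# Accumulate per-sample gradients over a mini-batch: grads lists are summed
# layer-wise; `scale` multiplies the increment (use 1/batch_size on the sum,
# or pass scale directly).
nn_acc_grads <- function(acc, grads, scale = 1) {
  if (is.null(acc)) {
    for (i in seq_along(grads)) {
      if (!is.null(grads[[i]])) {
        grads[[i]]$dw <- grads[[i]]$dw * scale
        grads[[i]]$db <- grads[[i]]$db * scale
      }
    }
    return(grads)
  }
  for (i in seq_along(grads)) {
    if (!is.null(grads[[i]])) {
      acc[[i]]$dw <- acc[[i]]$dw + grads[[i]]$dw * scale
      acc[[i]]$db <- acc[[i]]$db + grads[[i]]$db * scale
    }
  }
  acc
}

# Plain SGD with momentum; `state` carries velocities across calls.
nn_sgd_step <- function(net, grads, lr, momentum = 0.9, state = NULL) {
  if (is.null(state)) state <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.null(state[[i]])) {
      state[[i]] <- list(vw = 0 * net$layers[[i]]$w,
                         vb = 0 * net$layers[[i]]$b)
    }
    state[[i]]$vw <- momentum * state[[i]]$vw - lr * g$dw
    state[[i]]$vb <- momentum * state[[i]]$vb - lr * as.numeric(g$db)
    net$layers[[i]]$w <- net$layers[[i]]$w + state[[i]]$vw
    net$layers[[i]]$b <- net$layers[[i]]$b + state[[i]]$vb
  }
  list(net = net, state = state)
}

nn_n_weight_layers <- function(net) {
  sum(vapply(net$layers, function(l) l$type %in% c("conv", "dense"), logical(1)))
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
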