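# Stain classification.  Detected cells are first split into positively
# (brown, DAB) and negatively (blue, hematoxylin) stained by thresholds on
# the centroid-weighted hue and value of a 32 x 32 block, then positive
# cells are graded weak / moderate / strong by a small convolutional
# classifier.  Hue and value are expressed on the 0-255 scale, on which
# brown sits near 10-35 and blue near 140-175.

#' Positive/negative decision thresholds
#'
#' @param hue Weighted-hue threshold on the 0-255 scale: blocks with
#'   `wH > hue` (and not dark) are negative.
#' @param value Weighted-value threshold on the 0-255 scale: blocks darker
#'   than this (`wV < value`) are positive regardless of hue.
#' @return A `pn_thresholds` list.
#' @export
pn_thresholds <- function(hue = 40, value = 50) {
  if (hue < 0 || hue >= 256 || value < 0 || value > 255) {
    stop("thresholds must lie on the 0-255 scale")
  }
  structure(list(hue = hue, value = value), class = "pn_thresholds")
}

#' Extract a square block around a cell centroid
#'
#' Returns the `size x size` RGB block centred on the (0-based) centroid;
#' pixels falling outside the image are filled by reflection padding, so
#' blocks at image borders are fully defined.
#'
#' @param image RGB array `c(H, W, 3)`.
#' @param centroid Length-2 numeric `c(x, y)`, 0-based pixels.
#' @param size Block side length.
#' @return RGB array `c(size, size, 3)`.
#' @export
extract_patch <- function(image, centroid, size = 32) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- round(centroid[1]); cy <- round(centroid[2])
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    stop("centroid must lie inside the image")
  }
  half <- size %/% 2L
  rows <- reflect_index((cy + 1L - half):(cy + size - half), h)
  cols <- reflect_index((cx + 1L - half):(cx + size - half), w)
  image[rows, cols, , drop = FALSE]
}

#' Centroid-weighted hue and value of a block
#'
#' Converts the block to HSV (hue and value on the 0-255 scale) and
#' averages hue and value with weights decreasing linearly with the
#' Euclidean distance of each pixel from the block centre:
#' `w(p) = 1 - d(p)/d_max`, `d_max` being the half-diagonal of the block,
#' so pixels near the centroid dominate and every pixel keeps a strictly
#' positive weight.  Hue is averaged arithmetically (not circularly); both
#' stain families sit far from the hue wrap point.
#'
#' @param block Square RGB array, values in `[0, 1]`.
#' @return List with `wH` and `wV` (0-255 scale).
#' @export
weighted_hsv <- function(block) {
  d <- dim(block)
  stopifnot(length(d) == 3, d[3] == 3)
  hsv <- rgb_to_hsv255(block)
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  dist <- sqrt(outer((seq_len(d[1]) - ci)^2, (seq_len(d[2]) - cj)^2, "+"))
  dmax <- sqrt((d[1] / 2)^2 + (d[2] / 2)^2)
  w <- 1 - dist / dmax
  sw <- sum(w)
  list(wH = sum(w * hsv$h) / sw, wV = sum(w * hsv$v) / sw)
}

#' Classify a weighted colour as positively or negatively stained
#'
#' Two-step rule: (1) if the weighted value is below the value threshold
#' the block is dark and counts as positive regardless of hue; (2)
#' otherwise the hue decides, with `wH` at or below the hue threshold
#' positive (brown) and above it negative (blue).
#'
#' @param wc List with `wH`, `wV` as returned by [weighted_hsv()].
#' @param thresholds [pn_thresholds()].
#' @return `"P"` or `"N"`.
#' @export
classify_pn <- function(wc, thresholds = pn_thresholds()) {
  if (wc$wV < thresholds$value) return("P")
  if (wc$wH <= thresholds$hue) "P" else "N"
}

#' Training configuration for the weak/moderate/strong classifier
#'
#' Defaults follow the package's standard schedule: stochastic gradient
#' descent for 600 epochs, learning rate 1e-2 for the first 10 epochs and
#' 1e-4 thereafter, zero-mean Gaussian weight initialisation, and
#' horizontal-flip / random-crop augmentation.  Reduced epoch budgets are
#' appropriate for the synthetic benchmarks.
#'
#' @param epochs Training epochs (>= 1).
#' @param lr Learning rate per epoch, recycled to `epochs` values.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size; gradients are averaged over the
#'   batch before each update (the two-phase learning-rate schedule
#'   assumes batched updates; per-sample steps at 1e-2 are unstable).
#' @param seed RNG seed (weights, shuffling, augmentation, dropout).
#' @param augment Apply horizontal flips and random 28->32 crops.
#' @param widths Channel widths of the eight convolution layers.
#' @param dropout Dropout rate before the fully connected layer.
#' @param validation_fraction Held-out fraction used for the reported
#'   validation accuracy.
#' @return A `wms_config` list.
#' @export
wms_config <- function(epochs = 600, lr = NULL, momentum = 0, batch_size = 10,
                       seed = 1L, augment = TRUE,
                       widths = c(8, 8, 16, 16, 16, 16, 32, 32),
                       dropout = 0.25, validation_fraction = 0.15) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (is.null(lr)) lr <- c(rep(1e-2, min(10, epochs)),
                           rep(1e-4, max(0, epochs - 10)))
  lr <- rep_len(lr, epochs)
  if (any(lr <= 0)) stop("learning rates must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 widths = widths, dropout = dropout,
                 validation_fraction = validation_fraction),
            class = "wms_config")
}

# Nine weight layers: 8 conv(3x3)+ReLU in back-to-back pairs with 3
# maxpools, dropout, then the fully connected softmax output.
wms_spec <- function(widths, dropout) {
  w <- widths
  list(
    nn_conv(w[1]), nn_relu(),
    nn_conv(w[2]), nn_relu(),
    nn_maxpool(),
    nn_conv(w[3]), nn_relu(),
    nn_conv(w[4]), nn_relu(),
    nn_maxpool(),
    nn_conv(w[5]), nn_relu(),
    nn_conv(w[6]), nn_relu(),
    nn_maxpool(),
    nn_conv(w[7]), nn_relu(),
    nn_conv(w[8]), nn_relu(),
    nn_dropout(dropout),
    nn_flatten(),
    nn_dense(3L)
  )
}

wms_classes <- c("S", "M", "W") # ordered strongest first for tie-breaking

# Random 28x28 crop resized back to `size` by nearest neighbour.
random_crop_resize <- function(x, crop = 28L) {
  size <- dim(x)[1]
  r0 <- sample.int(size - crop + 1L, 1)
  c0 <- sample.int(size - crop + 1L, 1)
  xc <- x[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
  sel <- round(seq(1, crop, length.out = size))
  xc[sel, sel, , drop = FALSE]
}

#' Train the weak/moderate/strong staining classifier
#'
#' Fits the nine-layer convolutional classifier on labelled 32 x 32 RGB
#' patches of positive cells, with seeded SGD and optional augmentation
#' (horizontal flips, random 28 x 28 crops resized back; inputs are
#' normalised to `[-0.5, 0.5]`).
#'
#' @param patches Array `c(32, 32, 3, n)` or an `ihc_patchset` (its `N`
#'   patches, if any, are dropped).
#' @param labels Character vector in `{W, M, S}` (ignored when `patches`
#'   is an `ihc_patchset`).
#' @param cfg [wms_config()].
#' @return A `wms_model` with the fitted network, per-epoch training loss
#'   and held-out `val_accuracy`.
#' @export
train_wms <- function(patches, labels = NULL, cfg = wms_config()) {
  if (inherits(patches, "ihc_patchset")) {
    keep <- patches$label %in% wms_classes
    labels <- patches$label[keep]
    patches <- patches$x[, , , keep, drop = FALSE]
  }
  stopifnot(length(dim(patches)) == 4, dim(patches)[4] == length(labels))
  if (!all(labels %in% wms_classes)) {
    stop("labels must be in {W, M, S}")
  }
  if (!all(wms_classes %in% labels)) {
    stop("every class W, M, S must be present in the training data")
  }
  set.seed(cfg$seed)
  n <- length(labels)
  size <- dim(patches)[1]
  y <- match(labels, wms_classes)
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  net <- nn_init(wms_spec(cfg$widths, cfg$dropout), c(size, size, 3L))
  state <- NULL
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    tot <- 0
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (batch in batches) {
      acc <- NULL
      for (i in batch) {
        x <- patches[, , , i] - 0.5
        if (cfg$augment) {
          if (stats::runif(1) < 0.5) x <- x[, dim(x)[2]:1, , drop = FALSE]
          if (stats::runif(1) < 0.5) x <- random_crop_resize(x)
        }
        fwd <- nn_forward(net, x, train = TRUE)
        p <- softmax_vec(fwd$out)
        tot <- tot - log(max(p[y[i]], 1e-12))
        dlogits <- p
        dlogits[y[i]] <- dlogits[y[i]] - 1
        grads <- nn_backward(net, fwd$caches, dlogits)
        acc <- nn_acc_grads(acc, grads, 1 / length(batch))
      }
      upd <- nn_sgd_step(net, acc, cfg$lr[ep], cfg$momentum, state)
      net <- upd$net; state <- upd$state
    }
    history[ep] <- tot / length(ord)
  }
  model <- structure(list(net = net, classes = wms_classes, cfg = cfg,
                          history = history, val_accuracy = NA_real_),
                     class = "wms_model")
  if (n_val > 0) {
    pred <- vapply(val_idx, function(i) {
      classify_wms(model, patches[, , , i])
    }, character(1))
    model$val_accuracy <- mean(pred == labels[val_idx])
  }
  model
}

#' @export
print.wms_model <- function(x, ...) {
  cat("<wms_model> ", nn_n_weight_layers(x$net), " weight layers, ",
      length(x$history), " epochs, final loss ",
      signif(utils::tail(x$history, 1), 3), ", validation accuracy ",
      signif(x$val_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Class posterior of the weak/moderate/strong classifier
#'
#' @param model A trained [train_wms()] model.
#' @param block 32 x 32 RGB array in `[0, 1]`.
#' @return Named numeric vector of probabilities over `S`, `M`, `W`
#'   (sums to 1).
#' @export
wms_posterior <- function(model, block) {
  stopifnot(inherits(model, "wms_model"))
  if (is.null(model$net)) stop("untrained model")
  fwd <- nn_forward(model$net, block - 0.5, train = FALSE)
  stats::setNames(softmax_vec(fwd$out), model$classes)
}

#' Classify a positive cell block as weak, moderate or strong
#'
#' Argmax over the three class posteriors; exact ties break toward the
#' stronger class.
#'
#' @inheritParams wms_posterior
#' @return `"W"`, `"M"` or `"S"`.
#' @export
classify_wms <- function(model, block) {
  p <- wms_posterior(model, block)
  # classes are ordered strongest first, so which.max resolves ties upward
  model$classes[which.max(p)]
}

#' Assign a stain class to every detected cell
#'
#' For each cell a 32 x 32 block is extracted around its centroid; the
#' positive/negative rule assigns `N` directly, and positive cells are
#' passed to the weak/moderate/strong classifier.  Cell order is
#' preserved.  The classifier is only invoked when at least one cell is
#' positive, so an all-negative image never requires a trained model.
#'
#' @param image RGB array `c(H, W, 3)`.
#' @param cells Tibble of detections with 0-based `x`, `y` (from
#'   [extract_cells()]).
#' @param thresholds [pn_thresholds()].
#' @param wms_model A trained [train_wms()] model (may be `NULL` if no
#'   cell is positive).
#' @param patch_size Block side length.
#' @return `cells` with the `label` column filled (`N`, `W`, `M` or `S`).
#' @export
classify_cells <- function(image, cells, thresholds = pn_thresholds(),
                           wms_model = NULL, patch_size = 32) {
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) == 0) {
    cells$label <- character(0)
    return(cells)
  }
  labels <- character(nrow(cells))
  blocks <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    blocks[[i]] <- extract_patch(image, c(cells$x[i], cells$y[i]), patch_size)
    pn <- classify_pn(weighted_hsv(blocks[[i]]), thresholds)
    labels[i] <- if (pn == "N") "N" else NA_character_
  }
  pos <- which(is.na(labels))
  if (length(pos) > 0) {
    if (is.null(wms_model)) {
      stop("wms_model is required: ", length(pos), " cells are positive")
    }
    for (i in pos) labels[i] <- classify_wms(wms_model, blocks[[i]])
  }
  cells$label <- labels
  cells
}
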