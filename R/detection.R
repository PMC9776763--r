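# Cell detection: a compact convolutional regressor predicts a per-pixel
# score map encoding proximity to the nearest cell centre (a clipped,
# linearly decaying Euclidean distance transform), which is thresholded,
# split into instances by seeded watershed-style propagation, area-filtered
# and reduced to region centroids.

#' Detection parameters
#'
#' The constants governing score-map post-processing: the cell radius `R`
#' used for the score target and peak separation, the score threshold above
#' which pixels count as cell, and the region-area rule.
#'
#' @param cell_radius Cell radius `R` in pixels; the score target decays
#'   linearly from 1 at a centre to 0 at distance `R`.
#' @param score_threshold Scores at or above this value constitute cells.
#' @param min_region_area Area rule value in pixels^2.
#' @param area_rule `"min"` (default) removes regions *smaller* than
#'   `min_region_area` (watershed debris); `"max"` removes larger regions.
#' @param patch_size Side of the square training windows.
#' @param peak_separation Minimum distance between watershed seed peaks;
#'   defaults to `cell_radius / 2`.
#' @param smooth_sigma Gaussian sigma applied to the score map before peak
#'   seeding (regression maps are locally bumpy; smoothing keeps one seed
#'   per cell-sized hill).  Defaults to `cell_radius / 8`; 0 disables.
#'   Binarisation, region areas and centroids always use the raw map.
#' @return A `detection_params` list.
#' @export
detection_params <- function(cell_radius = 32, score_threshold = 0.2,
                             min_region_area = 240, area_rule = c("min", "max"),
                             patch_size = 64,
                             peak_separation = cell_radius / 2,
                             smooth_sigma = cell_radius / 8) {
  area_rule <- match.arg(area_rule)
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (score_threshold <= 0 || score_threshold >= 1) {
    stop("score_threshold must be in (0, 1)")
  }
  if (min_region_area <= 0) stop("min_region_area must be > 0")
  if (cell_radius <= 0) stop("cell_radius must be > 0")
  structure(list(
    cell_radius = cell_radius, score_threshold = score_threshold,
    min_region_area = min_region_area, area_rule = area_rule,
    patch_size = as.integer(patch_size), peak_separation = peak_separation,
    smooth_sigma = smooth_sigma
  ), class = "detection_params")
}

#' Build the regression target score map for annotated centroids
#'
#' For each pixel `p` the target is `s(p) = max(0, 1 - d(p)/R)` where
#' `d(p)` is the Euclidean distance to the nearest annotated centroid: a
#' linear cone of radius `R` around every cell centre, 1 at the centre,
#' clipped to 0 beyond `R`.
#'
#' @param centroids Data frame with 0-based pixel columns `x`, `y` (may
#'   have zero rows, giving an all-zero map).
#' @param image_shape `c(height, width)` in pixels.
#' @param R Cone radius in pixels.
#' @return A `score_map`: numeric `height x width` matrix in `[0, 1]`.
#' @export
build_score_target <- function(centroids, image_shape, R = 32) {
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  s <- matrix(0, h, w)
  if (nrow(centroids) > 0) {
    if (any(centroids$x < 0 | centroids$x > w - 1 |
            centroids$y < 0 | centroids$y > h - 1)) {
      stop("centroids must lie inside the image")
    }
    for (i in seq_len(nrow(centroids))) {
      cx <- centroids$x[i]; cy <- centroids$y[i]
      rows <- max(1L, floor(cy - R + 1)):min(h, ceiling(cy + R + 1))
      cols <- max(1L, floor(cx - R + 1)):min(w, ceiling(cx + R + 1))
      d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+"))
      s[rows, cols] <- pmax(s[rows, cols], pmax(0, 1 - d / R))
    }
  }
  structure(s, class = c("score_map", "matrix"))
}

as_score_map <- function(m) {
  structure(pmin(pmax(m, 0), 1), class = c("score_map", "matrix"))
}

#' Detector training configuration
#'
#' @param epochs Number of passes over the training windows.
#' @param lr Learning rate per epoch: recycled to `epochs` values. The
#'   default follows the two-phase schedule used throughout the package
#'   (1e-2 for the first 10 epochs, then 1e-4).
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size (gradients averaged per batch).
#' @param seed RNG seed covering weight initialisation, window sampling,
#'   shuffling and augmentation.
#' @param augment Use random horizontal flips of training windows.
#' @param widths Channel widths of the eight convolution layers.
#' @param validation_fraction Fraction of windows held out to report
#'   validation mean-squared error.
#' @return A `detector_config` list.
#' @export
detector_config <- function(epochs = 30, lr = NULL, momentum = 0,
                            batch_size = 1, seed = 1L, augment = TRUE,
                            widths = c(8, 8, 12, 12, 12, 12, 8, 8),
                            validation_fraction = 0.15) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (is.null(lr)) lr <- c(rep(1e-2, min(10, epochs)),
                           rep(1e-4, max(0, epochs - 10)))
  lr <- rep_len(lr, epochs)
  if (any(lr <= 0)) stop("learning rates must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 widths = widths,
                 validation_fraction = validation_fraction),
            class = "detector_config")
}

# Fully convolutional architecture: 8 conv(3x3) + ReLU blocks with 2
# maxpools and two nearest-upsample + conv stages back to input resolution,
# ending in a linear 1x1 conv regression output (<= 20 layers in total).
detector_spec <- function(widths) {
  w <- widths
  list(
    nn_conv(w[1]), nn_relu(),
    nn_conv(w[2]), nn_relu(),
    nn_maxpool(),
    nn_conv(w[3]), nn_relu(),
    nn_conv(w[4]), nn_relu(),
    nn_maxpool(),
    nn_conv(w[5]), nn_relu(),
    nn_upsample(2L),
    nn_conv(w[6]), nn_relu(),
    nn_upsample(2L),
    nn_conv(w[7]), nn_relu(),
    nn_conv(w[8]), nn_relu(),
    nn_conv(1L, k = 1L)
  )
}

# Extract a patch (window) and its target from scene + full target map.
# Window is clamped inside the image.  0-based centre (cx, cy).
window_at <- function(image, target, cx, cy, size) {
  h <- dim(image)[1]; w <- dim(image)[2]
  half <- size %/% 2L
  r0 <- min(max(round(cy) + 1L - half, 1L), h - size + 1L)
  c0 <- min(max(round(cx) + 1L - half, 1L), w - size + 1L)
  list(x = image[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE],
       y = target[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])
}

#' Train the cell-detection score-map regressor
#'
#' Extracts square windows centred on every annotated cell plus an equal
#' number of background windows (sampled at least `R` away from any
#' centroid), builds the cone-shaped score target for each scene, and fits
#' the fully convolutional regressor by stochastic gradient descent on the
#' per-pixel squared error.
#'
#' @param scenes List of `ihc_scene` objects, or a list of lists with
#'   elements `image` and `truth` (tibble with 0-based `x`, `y`).
#' @param params [detection_params()].
#' @param cfg [detector_config()].
#' @return A `cell_detector` with the fitted network, `params`, `cfg` and a
#'   per-epoch `history` (training MSE), plus `val_mse` and the validation
#'   target variance `val_baseline` (the MSE of the best constant
#'   predictor).
#' @export
train_detector <- function(scenes, params = detection_params(),
                           cfg = detector_config()) {
  stopifnot(length(scenes) >= 1)
  set.seed(cfg$seed)
  size <- params$patch_size
  xs <- list(); ys <- list()
  n_pos <- 0L
  for (sc in scenes) {
    image <- sc$image; truth <- sc$truth
    target <- build_score_target(truth, dim(image)[1:2], params$cell_radius)
    if (nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        wdw <- window_at(image, target, truth$x[i], truth$y[i], size)
        xs[[length(xs) + 1L]] <- wdw$x
        ys[[length(ys) + 1L]] <- wdw$y
        n_pos <- n_pos + 1L
      }
      # background windows, 1:1 with cell windows
      need <- nrow(truth)
      tries <- 0L
      while (need > 0 && tries < 200L * nrow(truth)) {
        tries <- tries + 1L
        cx <- stats::runif(1, 0, dim(image)[2] - 1)
        cy <- stats::runif(1, 0, dim(image)[1] - 1)
        d <- sqrt((truth$x - cx)^2 + (truth$y - cy)^2)
        if (min(d) < params$cell_radius) next
        wdw <- window_at(image, target, cx, cy, size)
        xs[[length(xs) + 1L]] <- wdw$x
        ys[[length(ys) + 1L]] <- wdw$y
        need <- need - 1L
      }
    }
  }
  if (n_pos == 0L) stop("no positive training windows: scenes have no cells")
  n <- length(xs)
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)

  net <- nn_init(detector_spec(cfg$widths), c(size, size, 3L))
  state <- NULL
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    tot <- 0
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (batch in batches) {
      acc <- NULL
      for (i in batch) {
        x <- xs[[i]] - 0.5
        y <- ys[[i]]
        if (cfg$augment && stats::runif(1) < 0.5) {
          x <- x[, dim(x)[2]:1, , drop = FALSE]
          y <- y[, ncol(y):1]
        }
        fwd <- nn_forward(net, x, train = TRUE)
        pred <- fwd$out[, , 1]
        err <- pred - y
        tot <- tot + mean(err^2)
        dout <- array(2 * err / length(err), dim = c(dim(err), 1L))
        grads <- nn_backward(net, fwd$caches, dout)
        acc <- nn_acc_grads(acc, grads, 1 / length(batch))
      }
      upd <- nn_sgd_step(net, acc, cfg$lr[ep], cfg$momentum, state)
      net <- upd$net; state <- upd$state
    }
    history[ep] <- tot / length(ord)
  }
  val_mse <- 0; val_base <- 0
  for (i in val_idx) {
    fwd <- nn_forward(net, xs[[i]] - 0.5, train = FALSE)
    val_mse <- val_mse + mean((fwd$out[, , 1] - ys[[i]])^2)
  }
  val_mse <- val_mse / n_val
  ally <- unlist(lapply(val_idx, function(i) ys[[i]]))
  val_base <- mean((ally - mean(ally))^2)
  structure(list(net = net, params = params, cfg = cfg, history = history,
                 val_mse = val_mse, val_baseline = val_base),
            class = "cell_detector")
}

#' @export
print.cell_detector <- function(x, ...) {
  cat("<cell_detector> ", nn_n_weight_layers(x$net), " weight layers, ",
      length(x$history), " training epochs, final train MSE ",
      signif(utils::tail(x$history, 1), 3),
      ", validation MSE ", signif(x$val_mse, 3),
      " (constant-predictor baseline ", signif(x$val_baseline, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Predict the score map for a whole image
#'
#' Runs the fully convolutional regressor over the image in one pass (no
#' patch stitching seams); the input is reflect-padded to a multiple of 4
#' (the network's downsampling factor) and the output cropped back and
#' clipped to `[0, 1]`.
#'
#' @param model A trained [train_detector()] model.
#' @param image RGB array `c(H, W, 3)` in `[0, 1]`.
#' @return A `score_map` matrix of the same height/width as `image`.
#' @export
predict_score_map <- function(model, image) {
  stopifnot(inherits(model, "cell_detector"))
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < 32 || w < 32) {
    stop("image smaller than the network's receptive field (32 px)")
  }
  padded <- pad_to_multiple(image, 4L)
  fwd <- nn_forward(model$net, padded - 0.5, train = FALSE)
  as_score_map(fwd$out[seq_len(h), seq_len(w), 1])
}

# 3x3 neighbourhood maximum with -Inf outside the border.
max_filter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  shift <- function(di, dj) {
    out <- matrix(-Inf, h, w)
    ri <- seq_len(h) + di; ci <- seq_len(w) + dj
    ok_r <- ri >= 1 & ri <= h; ok_c <- ci >= 1 & ci <= w
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  }
  res <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    res <- pmax(res, shift(di, dj))
  }
  res
}

# Seed peaks: local maxima of the map at or above `thr`, thinned greedily to
# a minimum separation, processed in descending score with ties broken by
# first occurrence in row-major order (y, then x).
find_peaks <- function(sm, thr, min_sep) {
  cand <- which(sm >= thr & sm >= max_filter3(sm), arr.ind = TRUE)
  if (nrow(cand) == 0) return(cand)
  score <- sm[cand]
  # row-major = by row (y) then column (x)
  ord <- order(-score, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  kept <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) > 0) {
      d2 <- (kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2
      if (any(d2 < min_sep^2)) next
    }
    keep[i] <- TRUE
    kept <- rbind(kept, cand[i, ])
  }
  cand[keep, , drop = FALSE]
}

#' Extract cell centroids from a score map
#'
#' Binarises the map at the score threshold, splits touching components by
#' watershed-style propagation seeded from local maxima of the map (minimum
#' peak separation `peak_separation`, ties broken in row-major order),
#' applies the region-area rule, and returns the surviving region
#' centroids.  Deterministic given the map and parameters; results are
#' sorted by `y` then `x`.
#'
#' @param score_map A `score_map` matrix (values in `[0, 1]`).
#' @param params [detection_params()].
#' @return A tibble of detected cells: 0-based `x`, `y` (region centroid),
#'   `area` (pixels^2), `score` (map value at the seed peak) and an empty
#'   `label` column filled later by [classify_cells()].
#' @export
extract_cells <- function(score_map, params = detection_params()) {
  sm <- unclass(score_map)
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0),
                          score = numeric(0), label = character(0))
  mask <- sm >= params$score_threshold
  if (!any(mask)) return(empty)
  seed_map <- if (params$smooth_sigma > 0) {
    EBImage::gblur(sm, sigma = params$smooth_sigma)
  } else {
    sm
  }
  peaks <- find_peaks(seed_map, params$score_threshold,
                      params$peak_separation)
  if (nrow(peaks) == 0) return(empty)
  seeds <- matrix(0L, nrow(sm), ncol(sm))
  seeds[peaks] <- seq_len(nrow(peaks))
  labels <- EBImage::imageData(EBImage::propagate(
    x = sm, seeds = seeds, mask = mask
  ))
  ids <- seq_len(nrow(peaks))
  area <- tabulate(labels[labels > 0], nbins = nrow(peaks))
  keep <- if (params$area_rule == "min") {
    area >= params$min_region_area
  } else {
    area <= params$min_region_area
  }
  keep <- keep & area > 0
  if (!any(keep)) return(empty)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[idx]
  cx <- tapply(idx[, 2] - 1, lab, mean)
  cy <- tapply(idx[, 1] - 1, lab, mean)
  got <- as.integer(names(cx))
  res <- tibble::tibble(
    x = as.numeric(cx), y = as.numeric(cy),
    area = area[got],
    score = sm[peaks[got, , drop = FALSE]],
    label = NA_character_
  )[keep[got], ]
  dplyr::arrange(res, .data$y, .data$x)
}

#' @export
print.score_map <- function(x, ...) {
  cat("<score_map> ", ncol(x), "x", nrow(x), " px, range [",
      signif(min(x), 3), ", ", signif(max(x), 3), "]\n", sep = "")
  invisible(x)
}
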