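# Synthetic ER-IHC field generator.  Fields contain elliptical nuclei in two
# stain families: hematoxylin-like negatives (blue, N) and DAB-like positives
# at three darkness levels (weak W, moderate M, strong S).  Every nucleus is
# returned as exact ground truth so detection, classification and scoring can
# be trained and tested end to end with no external data.
#
# Coordinates are 0-based pixels (x = column, y = row) throughout.

#' Specification of a synthetic stained field
#'
#' Bundles and validates the parameters of one simulated field: image size,
#' per-class nucleus counts, nucleus radius range, allowed overlap,
#' background colour, additive noise and the RNG seed.
#'
#' @param width,height Image size in pixels.
#' @param n_cells Named integer vector of nucleus counts, names `N`, `W`,
#'   `M`, `S` (negative, weak, moderate, strong).
#' @param radius_range Length-2 numeric, min/max ellipse semi-axis in pixels.
#' @param max_overlap_fraction Allowed overlap between neighbouring nuclei in
#'   `[0, 1]`: 0 forbids touching, 1 allows coincident centres. Placement is
#'   by rejection sampling on centre distance.
#' @param background Background colour, RGB in `[0, 1]` (default a warm
#'   near-white, as in eosin-tinged tissue background).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   8-bit intensity units.
#' @param seed Integer RNG seed; a fixed seed makes the rendered field and
#'   its ground truth byte-identical across runs.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 320, height = 320,
                       n_cells = c(N = 30, W = 8, M = 8, S = 8),
                       radius_range = c(12, 20),
                       max_overlap_fraction = 0.1,
                       background = c(238, 225, 215) / 255,
                       noise_sd = 3,
                       seed = 1L) {
  counts <- c(N = 0L, W = 0L, M = 0L, S = 0L)
  if (length(n_cells) > 0) {
    if (is.null(names(n_cells)) || !all(names(n_cells) %in% names(counts))) {
      stop("n_cells must be named with labels among N, W, M, S")
    }
    counts[names(n_cells)] <- as.integer(n_cells)
  }
  if (any(counts < 0)) stop("n_cells counts must be >= 0")
  if (length(radius_range) != 2 || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2]) {
    stop("radius_range must be a positive increasing pair")
  }
  if (max_overlap_fraction < 0 || max_overlap_fraction > 1) {
    stop("max_overlap_fraction must be in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(width >= 1, height >= 1, length(background) == 3)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_cells = counts, radius_range = as.numeric(radius_range),
    max_overlap_fraction = max_overlap_fraction,
    background = as.numeric(background), noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Per-class stain colour model
#'
#' Mean and spread of nucleus colour per class, sampled in HSV (hue and
#' value on the 0-255 scale, saturation in `[0, 1]`).  Defaults put the
#' negative class in the blue family (hue about 155) and the three positive
#' classes in the brown family (hue about 20) at decreasing value
#' (strong darkest), so the positive/negative hue/value thresholds used by
#' [classify_pn()] separate the families cleanly.
#'
#' @return A tibble with one row per class `N`, `W`, `M`, `S`.
#' @export
class_color_model <- function() {
  tibble::tibble(
    label = c("N", "W", "M", "S"),
    hue_mean = c(155, 20, 20, 20),
    hue_sd = c(4, 4, 4, 4),
    sat_mean = c(0.40, 0.50, 0.55, 0.60),
    sat_sd = c(0.05, 0.05, 0.05, 0.05),
    val_mean = c(165, 200, 140, 64),
    val_sd = c(10, 8, 10, 10)
  )
}

# Draw per-nucleus base colour for a class label (uses the current RNG).
sample_class_color <- function(label, colors) {
  row <- colors[colors$label == label, ]
  c(
    h = stats::rnorm(1, row$hue_mean, row$hue_sd),
    s = min(max(stats::rnorm(1, row$sat_mean, row$sat_sd), 0.05), 1),
    v = stats::rnorm(1, row$val_mean, row$val_sd)
  )
}

# Paint one elliptical nucleus onto `img` (modified copy returned).
# cx, cy 0-based centre; a, b semi-axes; theta rotation in radians.
render_nucleus <- function(img, cx, cy, a, b, theta, base_hsv) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- max(a, b)
  rows <- max(1L, floor(cy - r + 1)):min(h, ceiling(cy + r + 1))
  cols <- max(1L, floor(cx - r + 1)):min(w, ceiling(cx + r + 1))
  gx <- rep(cols - 1, each = length(rows)) - cx
  gy <- rep(rows - 1, times = length(cols)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  n <- sum(inside)
  if (n == 0) return(img)
  rgb <- hsv255_to_rgb(
    base_hsv["h"] + stats::rnorm(n, 0, 2),
    base_hsv["s"] + stats::rnorm(n, 0, 0.02),
    base_hsv["v"] + stats::rnorm(n, 0, 4)
  )
  ri <- rep(rows, times = length(cols))[inside]
  ci <- rep(cols, each = length(rows))[inside]
  img[cbind(ri, ci, 1L)] <- rgb[, 1]
  img[cbind(ri, ci, 2L)] <- rgb[, 2]
  img[cbind(ri, ci, 3L)] <- rgb[, 3]
  img
}

#' Generate a synthetic stained field with exact ground truth
#'
#' Renders the requested number of nuclei per class as filled, mildly
#' rotated ellipses with per-pixel colour jitter, on a near-white
#' background, then adds Gaussian noise and quantises to 8-bit levels.
#' Placement is rejection sampling on centre distance: two nuclei may
#' overlap by at most `max_overlap_fraction` of their combined radii.
#'
#' @param spec A [scene_spec()].
#' @param colors Class colour model, see [class_color_model()].
#' @return An object of class `ihc_scene`: list with `image` (H x W x 3
#'   array in `[0, 1]`), `truth` (tibble `x`, `y`, `label`, `a`, `b`,
#'   `theta`; 0-based pixel coordinates) and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(n_cells = c(N = 5, S = 2), seed = 7))
#' nrow(sc$truth)
#' @export
generate_scene <- function(spec = scene_spec(), colors = class_color_model()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  labels <- rep(names(spec$n_cells), times = spec$n_cells)
  n <- length(labels)
  img <- array(rep(spec$background, each = spec$height * spec$width),
               c(spec$height, spec$width, 3))
  truth <- tibble::tibble(
    x = numeric(0), y = numeric(0), label = character(0),
    a = numeric(0), b = numeric(0), theta = numeric(0)
  )
  if (n > 0) {
    labels <- sample(labels) # interleave classes spatially
    rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]
    placed <- matrix(numeric(0), ncol = 3) # cx, cy, r
    rows <- vector("list", n)
    max_attempts <- 300L * n
    attempts <- 0L
    for (i in seq_len(n)) {
      a <- stats::runif(1, rmin, rmax)
      b <- stats::runif(1, rmin, rmax)
      theta <- stats::runif(1, 0, pi)
      r <- max(a, b)
      if (spec$width - 1 < 2 * r || spec$height - 1 < 2 * r) {
        stop("infeasible packing: nuclei larger than the field")
      }
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("infeasible packing: could not place ", n,
               " nuclei at max_overlap_fraction = ",
               spec$max_overlap_fraction)
        }
        cx <- stats::runif(1, r, spec$width - 1 - r)
        cy <- stats::runif(1, r, spec$height - 1 - r)
        if (nrow(placed) == 0) break
        d <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        minsep <- (1 - spec$max_overlap_fraction) * (placed[, 3] + r)
        if (all(d >= minsep)) break
      }
      placed <- rbind(placed, c(cx, cy, r))
      rows[[i]] <- tibble::tibble(
        x = cx, y = cy, label = labels[i], a = a, b = b, theta = theta
      )
      img <- render_nucleus(img, cx, cy, a, b, theta,
                            sample_class_color(labels[i], colors))
    }
    truth <- dplyr::bind_rows(rows)
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd / 255)
  }
  structure(list(image = quantise8(img), truth = truth, spec = spec),
            class = "ihc_scene")
}

#' @export
print.ihc_scene <- function(x, ...) {
  cat("<ihc_scene> ", dim(x$image)[2], "x", dim(x$image)[1],
      " px, ", nrow(x$truth), " nuclei (",
      paste(names(table(x$truth$label)), table(x$truth$label),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Generate a balanced set of labelled single-nucleus patches
#'
#' Renders `n_per_class` nuclei per class, each centred in its own patch,
#' for training and testing the staining-intensity classifier.
#'
#' @param n_per_class Patches per class (> 0).
#' @param patch_size Patch side length in pixels.
#' @param seed Integer RNG seed (fixed seed gives identical patch bytes).
#' @param colors Class colour model.
#' @param radius_range,background,noise_sd Rendering parameters, as in
#'   [scene_spec()].
#' @return An `ihc_patchset`: list with `x` (array
#'   `patch_size x patch_size x 3 x n`) and `label` (character vector).
#' @export
generate_patchset <- function(n_per_class, patch_size = 32, seed = 1L,
                              colors = class_color_model(),
                              radius_range = c(12, 20),
                              background = c(238, 225, 215) / 255,
                              noise_sd = 3) {
  if (n_per_class <= 0) stop("n_per_class must be > 0")
  patch_size <- as.integer(patch_size)
  set.seed(seed)
  canvas <- patch_size + 16L
  ctr <- (canvas - 1) / 2 # 0-based centre of the canvas
  labels <- rep(c("N", "W", "M", "S"), each = n_per_class)
  n <- length(labels)
  x <- array(0, c(patch_size, patch_size, 3, n))
  lo <- (canvas - patch_size) %/% 2L + 1L
  sel <- lo:(lo + patch_size - 1L)
  for (i in seq_len(n)) {
    img <- array(rep(background, each = canvas * canvas), c(canvas, canvas, 3))
    a <- stats::runif(1, radius_range[1], radius_range[2])
    b <- stats::runif(1, radius_range[1], radius_range[2])
    theta <- stats::runif(1, 0, pi)
    img <- render_nucleus(img, ctr, ctr, a, b, theta,
                          sample_class_color(labels[i], colors))
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd / 255)
    x[, , , i] <- quantise8(img)[sel, sel, ]
  }
  structure(list(x = x, label = labels), class = "ihc_patchset")
}

#' Write / read centroid annotations
#'
#' Annotations are CSV files with mandatory header `x,y,label`: 0-based
#' integer pixel coordinates (x = column, y = row) and labels in
#' `{N, W, M, S}` (the label may be empty for detections not yet
#' classified).  The round trip is lossless for integer centroids.
#'
#' @param truth A data frame with columns `x`, `y`, `label`.
#' @param path File path.
#' @return `write_annotations` returns `path` invisibly;
#'   `read_annotations` returns a tibble `x`, `y`, `label`.
#' @export
write_annotations <- function(truth, path) {
  stopifnot(all(c("x", "y", "label") %in% names(truth)))
  lab <- as.character(truth$label)
  lab[is.na(lab)] <- "" # unclassified detections
  out <- data.frame(
    x = as.integer(round(truth$x)),
    y = as.integer(round(truth$y)),
    label = lab
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty annotation file: ", path)
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!identical(header[1:3], c("x", "y", "label"))) {
    stop("annotation file must start with header 'x,y,label': ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(tibble::tibble(x = integer(0), y = integer(0), label = character(0)))
  }
  parts <- strsplit(body, ",")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line_no <- i + 1L # account for the header line
    if (length(p) < 2 || length(p) > 3) {
      stop("malformed annotation row at line ", line_no)
    }
    x <- suppressWarnings(as.numeric(p[1]))
    y <- suppressWarnings(as.numeric(p[2]))
    if (is.na(x) || is.na(y)) {
      stop("non-numeric coordinates at line ", line_no)
    }
    lab <- if (length(p) == 3) trimws(p[3]) else ""
    if (!lab %in% c("N", "W", "M", "S", "")) {
      stop("invalid label '", lab, "' at line ", line_no,
           " (expected N, W, M or S)")
    }
  }
  xs <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  ys <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  labs <- vapply(parts, function(p) {
    if (length(p) == 3) trimws(p[3]) else NA_character_
  }, character(1))
  labs[labs == ""] <- NA_character_
  tibble::tibble(x = as.integer(xs), y = as.integer(ys), label = labs)
}
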