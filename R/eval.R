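# Evaluation harness: whole-image tiling, the full detection ->
# classification -> scoring pipeline, centroid matching, detection and
# confusion-matrix metrics, and slide-level Allred agreement statistics.
# A bundled reference cohort (40 ER-IHC whole-slide evaluations with
# pathologist scores and automated class proportions, plus detection and
# classification tables from the same published evaluation) supports exact
# regression checks of the scoring rules.

#' Split an image into high-power-field tiles
#'
#' Non-overlapping grid by default; partial tiles at the right/bottom edge
#' are included, so tile offsets and sizes partition every pixel exactly
#' once at `overlap = 0`.
#'
#' @param image RGB array `c(H, W, 3)` (a plain `H x W` matrix also
#'   works).
#' @param field_size Tile side length in pixels (must not exceed the
#'   image).
#' @param overlap Overlap between neighbouring tiles in pixels.
#' @return A tibble with 0-based offsets `x0`, `y0`, sizes `width`,
#'   `height`, and a list-column `tile` holding each sub-image.
#' @export
tile_image <- function(image, field_size, overlap = 0) {
  h <- dim(image)[1]; w <- dim(image)[2]
  field_size <- as.integer(field_size)
  if (field_size > h || field_size > w) {
    stop("field_size must not exceed the image size")
  }
  if (overlap < 0 || overlap >= field_size) {
    stop("overlap must be in [0, field_size)")
  }
  stride <- field_size - as.integer(overlap)
  starts <- function(n) {
    s <- seq.int(0L, max(0L, n - 1L), by = stride)
    s[s < n]
  }
  grid <- expand.grid(y0 = starts(h), x0 = starts(w))
  tiles <- purrr::map2(grid$y0, grid$x0, function(y0, x0) {
    rows <- (y0 + 1L):min(h, y0 + field_size)
    cols <- (x0 + 1L):min(w, x0 + field_size)
    if (length(dim(image)) == 3) {
      image[rows, cols, , drop = FALSE]
    } else {
      image[rows, cols, drop = FALSE]
    }
  })
  tibble::tibble(
    x0 = grid$x0, y0 = grid$y0,
    width = vapply(tiles, function(t) dim(t)[2], integer(1)),
    height = vapply(tiles, function(t) dim(t)[1], integer(1)),
    tile = tiles
  )
}

# Merge detections closer than `tol` pixels (seam duplicates) to their mean.
dedupe_cells <- function(cells, tol = 8) {
  if (nrow(cells) <= 1) return(cells)
  keep <- rep(TRUE, nrow(cells))
  for (i in seq_len(nrow(cells) - 1)) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(cells)) > i)
    if (length(j) == 0) next
    d <- sqrt((cells$x[j] - cells$x[i])^2 + (cells$y[j] - cells$y[i])^2)
    dup <- j[d < tol]
    if (length(dup) > 0) {
      cells$x[i] <- mean(c(cells$x[i], cells$x[dup]))
      cells$y[i] <- mean(c(cells$y[i], cells$y[dup]))
      keep[dup] <- FALSE
    }
  }
  cells[keep, ]
}

#' Run the full pipeline on one image
#'
#' Tiles the image into high-power fields, predicts a score map and
#' extracts cells per field (each field is expanded by a context margin so
#' nuclei straddling field borders are seen whole; detections are kept
#' only inside their core field and residual seam duplicates within 8 px
#' are merged), classifies every detection, and converts the class
#' composition into an Allred score.  Deterministic for fixed inputs.
#'
#' @param image RGB array `c(H, W, 3)` in `[0, 1]`.
#' @param detector A trained [train_detector()] model.
#' @param wms_model A trained [train_wms()] model.
#' @param params [detection_params()].
#' @param thresholds [pn_thresholds()].
#' @param field_size High-power-field side length in pixels.
#' @param context Context margin added around each field for detection.
#' @return A `slide_report`: list with `cells` (classified detections),
#'   `summary` ([slide_summary()]) and `allred` ([allred()]).
#' @export
run_slide <- function(image, detector, wms_model,
                      params = detection_params(),
                      thresholds = pn_thresholds(),
                      field_size = 256, context = 32) {
  h <- dim(image)[1]; w <- dim(image)[2]
  field_size <- min(field_size, h, w)
  offsets <- tile_image(image, field_size)[, c("x0", "y0", "width", "height")]
  all_cells <- list()
  for (k in seq_len(nrow(offsets))) {
    x0 <- offsets$x0[k]; y0 <- offsets$y0[k]
    rows <- max(1L, y0 + 1L - context):min(h, y0 + offsets$height[k] + context)
    cols <- max(1L, x0 + 1L - context):min(w, x0 + offsets$width[k] + context)
    sub <- image[rows, cols, , drop = FALSE]
    cells <- extract_cells(predict_score_map(detector, sub), params)
    if (nrow(cells) == 0) next
    cells$x <- cells$x + cols[1] - 1L
    cells$y <- cells$y + rows[1] - 1L
    core <- cells$x >= x0 & cells$x < x0 + offsets$width[k] &
      cells$y >= y0 & cells$y < y0 + offsets$height[k]
    all_cells[[length(all_cells) + 1L]] <- cells[core, ]
  }
  cells <- if (length(all_cells)) dplyr::bind_rows(all_cells) else
    tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0),
                   score = numeric(0), label = character(0))
  cells <- dedupe_cells(dplyr::arrange(cells, .data$y, .data$x))
  cells <- classify_cells(image, cells, thresholds, wms_model)
  counts <- table(factor(cells$label, levels = c("N", "W", "M", "S")))
  summ <- slide_summary(N = counts[["N"]], W = counts[["W"]],
                        M = counts[["M"]], S = counts[["S"]])
  res <- if (summ$total > 0) allred(summ) else NULL
  structure(list(cells = cells, summary = summ, allred = res),
            class = "slide_report")
}

#' @export
print.slide_report <- function(x, ...) {
  cat("<slide_report> ", nrow(x$cells), " cells (N=", x$summary$N,
      ", W=", x$summary$W, ", M=", x$summary$M, ", S=", x$summary$S, ")\n",
      sep = "")
  if (!is.null(x$allred)) print(x$allred)
  invisible(x)
}

#' @export
glance.slide_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells), N = x$summary$N, W = x$summary$W,
    M = x$summary$M, S = x$summary$S, er_pct = x$summary$er_pct,
    pscore = if (is.null(x$allred)) NA_integer_ else x$allred$pscore,
    iscore = if (is.null(x$allred)) NA_integer_ else x$allred$iscore,
    score = if (is.null(x$allred)) NA_integer_ else x$allred$score,
    actionable = if (is.null(x$allred)) NA else x$allred$actionable
  )
}

#' Match predicted to ground-truth centroids
#'
#' One-to-one greedy matching by ascending pairwise distance; pairs
#' farther apart than `tol` are rejected.  Unmatched predictions are false
#' positives, unmatched truths false negatives.
#'
#' @param predicted,truth Data frames with 0-based `x`, `y` columns.
#' @param tol Matching tolerance in pixels (> 0).
#' @return A `match_result`: list with counts `tp`, `fp`, `fn` and a
#'   tibble `pairs` (`pred`, `truth` row indices, `dist`).
#' @export
match_detections <- function(predicted, truth, tol = 16) {
  if (tol <= 0) stop("tol must be > 0")
  np <- nrow(predicted); nt <- nrow(truth)
  pairs <- tibble::tibble(pred = integer(0), truth = integer(0),
                          dist = numeric(0))
  if (np > 0 && nt > 0) {
    d <- outer(predicted$x, truth$x, "-")^2 + outer(predicted$y, truth$y, "-")^2
    cand <- which(d <= tol^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_p[i] || used_t[j]) next
        used_p[i] <- TRUE; used_t[j] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(
          pred = as.integer(i), truth = as.integer(j),
          dist = sqrt(d[i, j])
        ))
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = nt - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' Detection recall and precision from match counts
#'
#' @param tp,fp,fn True positive, false positive and false negative
#'   counts (`tp + fn` and `tp + fp` must be positive).
#' @return A tibble with `tp`, `fp`, `fn`, `recall = tp/(tp+fn)` and
#'   `precision = tp/(tp+fp)`.
#' @export
detection_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0")
  if (tp + fn == 0) stop("recall undefined: tp + fn = 0")
  if (tp + fp == 0) stop("precision undefined: tp + fp = 0")
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 recall = tp / (tp + fn), precision = tp / (tp + fp))
}

#' Accuracy, PPV and TPR from a labelled confusion matrix
#'
#' Rows are true labels (and may include spill-over rows such as
#' `Negative` or `Non-Tumor` for cells that should not have reached this
#' classifier), columns are predicted labels.  Accuracy is the sum of the
#' diagonal cells (true rows that have a matching predicted column)
#' over the total count; `exclude_rows` drops spill-over rows first,
#' giving the "only true cells" variant.  PPV is per predicted column,
#' TPR per true row.
#'
#' @param cm Integer matrix with row and column dimnames.
#' @param exclude_rows Character vector of row labels to drop.
#' @return List with `accuracy`, named `ppv` and named `tpr`.
#' @export
confusion_metrics <- function(cm, exclude_rows = NULL) {
  if (length(cm) == 0 || sum(cm) == 0) stop("empty confusion matrix")
  if (any(cm < 0)) stop("confusion matrix entries must be >= 0")
  if (!is.null(exclude_rows)) {
    cm <- cm[!rownames(cm) %in% exclude_rows, , drop = FALSE]
  }
  labels <- intersect(rownames(cm), colnames(cm))
  diag_sum <- sum(vapply(labels, function(l) cm[l, l], numeric(1)))
  accuracy <- diag_sum / sum(cm)
  ppv <- vapply(labels, function(l) cm[l, l] / sum(cm[, l]), numeric(1))
  tpr <- vapply(labels, function(l) cm[l, l] / sum(cm[l, ]), numeric(1))
  list(accuracy = accuracy, ppv = ppv, tpr = tpr)
}

#' Slide-level agreement between manual and automated Allred scores
#'
#' @param manual,automated Equal-length vectors of Allred scores (values
#'   in `{0, 2..8}`).
#' @param actionable_threshold Scores at or above this value recommend
#'   hormonal therapy.
#' @return An `allred_agreement`: `n`, `exact` (identical scores),
#'   `diff_histogram` (tibble of |manual - automated| counts, exhaustive
#'   and disjoint), `treatment_agreement` (count) and
#'   `treatment_accuracy_pct`.
#' @export
agreement_stats <- function(manual, automated, actionable_threshold = 3) {
  if (length(manual) != length(automated)) {
    stop("manual and automated score lists must have equal length")
  }
  ok <- function(s) all(s %in% c(0, 2:8))
  if (!ok(manual) || !ok(automated)) {
    stop("scores must be in {0, 2..8}")
  }
  n <- length(manual)
  d <- abs(manual - automated)
  hist <- tibble::tibble(
    diff = 0:8,
    count = vapply(0:8, function(k) sum(d == k), integer(1))
  )
  agree <- sum((manual >= actionable_threshold) ==
               (automated >= actionable_threshold))
  structure(list(
    n = n, exact = sum(d == 0), diff_histogram = hist,
    diff_gt2 = sum(d > 2),
    treatment_agreement = agree,
    treatment_accuracy_pct = 100 * agree / n,
    manual = manual, automated = automated
  ), class = "allred_agreement")
}

#' @export
print.allred_agreement <- function(x, ...) {
  cat("<allred_agreement> n = ", x$n, ": ", x$exact, " exact, ",
      sum(x$diff_histogram$count[x$diff_histogram$diff == 1]), " off by 1, ",
      sum(x$diff_histogram$count[x$diff_histogram$diff == 2]), " off by 2, ",
      x$diff_gt2, " off by >2; treatment agreement ",
      x$treatment_agreement, "/", x$n, " = ",
      round(x$treatment_accuracy_pct, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.allred_agreement <- function(x, ...) x$diff_histogram

#' @export
glance.allred_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, exact = x$exact,
                 treatment_agreement = x$treatment_agreement,
                 treatment_accuracy_pct = x$treatment_accuracy_pct)
}

ref_path <- function(file) {
  system.file("extdata", file, package = "erallred", mustWork = TRUE)
}

#' Bundled reference evaluation tables
#'
#' A published 40-slide ER-IHC reference evaluation transcribed into plain
#' CSV: per-slide pathologist (manual) Allred components and automated ER
#' percentage plus strong/moderate/weak proportions
#' (`reference_slides()`; slide 05459 is flagged `consistent = FALSE`
#' because its printed weak proportion exceeds its printed ER percentage),
#' per-image detection counts (`reference_detection()`), and
#' positive/negative and weak/moderate/strong confusion matrices from the
#' same evaluation (`reference_pn_confusion()`,
#' `reference_wms_confusion()`), with spill-over rows for
#' negative/non-tumor cells wrongly passed on by earlier stages.
#'
#' @return `reference_slides()` and `reference_detection()` return
#'   tibbles; the confusion loaders return labelled integer matrices.
#' @export
reference_slides <- function() {
  tibble::as_tibble(utils::read.csv(
    ref_path("reference_slides.csv"),
    colClasses = c(image_id = "character")
  ))
}

#' @rdname reference_slides
#' @export
reference_detection <- function() {
  tibble::as_tibble(utils::read.csv(
    ref_path("reference_detection.csv"),
    colClasses = c(image_id = "character")
  ))
}

read_confusion <- function(file) {
  df <- utils::read.csv(ref_path(file), check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname reference_slides
#' @export
reference_pn_confusion <- function() read_confusion("reference_pn_confusion.csv")

#' @rdname reference_slides
#' @export
reference_wms_confusion <- function() read_confusion("reference_wms_confusion.csv")
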