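# Evaluation harness: tiling, matching, metrics, agreement statistics and
# the whole-slide pipeline.

test_that("tiling partitions the image with partial edge tiles", {
  img <- matrix(0, 1000, 1000)
  t4 <- tile_image(img, 500)
  expect_equal(nrow(t4), 4)
  expect_true(all(t4$width == 500 & t4$height == 500))

  img2 <- matrix(0, 1000, 1001)
  t6 <- tile_image(img2, 500)
  expect_equal(nrow(t6), 6)
  expect_true(any(t6$width == 1))
  # offsets cover every pixel exactly once
  cover <- matrix(0L, 1000, 1001)
  for (k in seq_len(nrow(t6))) {
    rows <- (t6$y0[k] + 1):(t6$y0[k] + t6$height[k])
    cols <- (t6$x0[k] + 1):(t6$x0[k] + t6$width[k])
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover == 1L))
  expect_error(tile_image(img, 2000), "field_size")
})

brute_force_best_matching <- function(pred, truth, tol) {
  # exhaustive one-to-one assignment over all permutations (small n only)
  n <- nrow(pred); m <- nrow(truth)
  stopifnot(n <= 7)
  d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  best <- 0L
  idx <- seq_len(m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (p in perms(idx)) {
    k <- min(n, m)
    matched <- sum(d[cbind(seq_len(k), p[seq_len(k)])] <= tol)
    best <- max(best, matched)
  }
  best
}

test_that("greedy matching handles identity, emptiness, and jittered grids", {
  pts <- tibble::tibble(x = c(10, 40, 70, 10, 40), y = c(10, 10, 10, 40, 40))
  m0 <- match_detections(pts, pts, tol = 16)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(5L, 0L, 0L))
  m1 <- match_detections(pts[0, ], pts, tol = 16)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(0L, 0L, 5L))
  # jitter below tol/2 must keep everything matched (checked against the
  # exhaustive assignment oracle)
  set.seed(5)
  jit <- pts
  jit$x <- jit$x + runif(5, -7, 7)
  jit$y <- jit$y + runif(5, -7, 7)
  m2 <- match_detections(jit, pts, tol = 16)
  expect_equal(m2$tp, brute_force_best_matching(jit, pts, 16))
  expect_equal(m2$tp, 5L)
  expect_error(match_detections(pts, pts, tol = 0), "tol")
})

test_that("match counts conserve prediction and truth totals", {
  set.seed(31)
  for (rep in 1:5) {
    np <- sample(0:12, 1); nt <- sample(1:12, 1)
    pred <- tibble::tibble(x = runif(np, 0, 100), y = runif(np, 0, 100))
    truth <- tibble::tibble(x = runif(nt, 0, 100), y = runif(nt, 0, 100))
    m <- match_detections(pred, truth, tol = 20)
    expect_equal(m$tp + m$fp, np)
    expect_equal(m$tp + m$fn, nt)
    if (nrow(m$pairs) > 0) {
      expect_false(any(duplicated(m$pairs$pred)))
      expect_false(any(duplicated(m$pairs$truth)))
      expect_true(all(m$pairs$dist <= 20))
    }
  }
})

test_that("detection metrics implement recall and precision with guards", {
  dm <- detection_metrics(107, 4, 5)
  expect_equal(round(dm$recall, 2), 0.96)
  expect_equal(round(dm$precision, 2), 0.96)
  expect_error(detection_metrics(0, 0, 5), "precision")
  expect_error(detection_metrics(0, 5, 0), "recall")
  expect_error(detection_metrics(-1, 0, 5), ">= 0")
})

test_that("confusion metrics handle identity and label permutations", {
  id <- diag(5)
  dimnames(id) <- list(letters[1:5], letters[1:5])
  m <- confusion_metrics(id)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$ppv == 1) && all(m$tpr == 1))

  set.seed(8)
  cm <- matrix(rpois(9, 20), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  perm <- c(3, 1, 2)
  cm2 <- cm[perm, perm]
  expect_equal(confusion_metrics(cm)$accuracy,
               confusion_metrics(cm2)$accuracy)
  expect_equal(confusion_metrics(cm)$ppv[c("a", "b", "c")],
               confusion_metrics(cm2)$ppv[c("a", "b", "c")])
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("agreement statistics are exhaustive and validate inputs", {
  s <- c(0, 2, 3, 5, 8, 7)
  ag <- agreement_stats(s, s)
  expect_equal(ag$exact, 6)
  expect_equal(ag$treatment_accuracy_pct, 100)
  expect_equal(sum(ag$diff_histogram$count), 6)
  expect_error(agreement_stats(c(0, 2), c(2)), "equal length")
  expect_error(agreement_stats(c(1, 2), c(2, 2)), "scores")
})

test_that("the bundled reference tables load with their printed shapes", {
  rs <- reference_slides()
  expect_equal(nrow(rs), 40)
  expect_equal(sum(!rs$consistent), 1)
  expect_equal(rs$image_id[!rs$consistent], "05459")
  rd <- reference_detection()
  expect_equal(nrow(rd), 15)
  overall <- rd[rd$experiment == "Overall", ]
  expect_equal(overall$tp + 0, 1328)
  expect_equal(sum(rd$tp[rd$experiment != "Overall"]), 1328)
  expect_equal(sum(rd$fp[rd$experiment != "Overall"]), 62)
  expect_equal(sum(rd$fn[rd$experiment != "Overall"]), 97)
  expect_equal(dim(reference_pn_confusion()), c(3, 2))
  expect_equal(dim(reference_wms_confusion()), c(5, 3))
})

test_that("run_slide is deterministic and scores an easy field correctly", {
  det <- shared_detector()
  wms <- shared_wms()
  sc <- generate_scene(scene_spec(width = 320, height = 320,
                                  n_cells = c(N = 12, W = 10, M = 4, S = 26),
                                  seed = 4242))
  a <- run_slide(sc$image, det, wms)
  b <- run_slide(sc$image, det, wms)
  expect_identical(glance(a), glance(b))
  expect_identical(a$cells, b$cells)
  # 40/52 positive, strong-dominant: proportion 5 + intensity 3
  expect_equal(a$allred$score, 8L)
})
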