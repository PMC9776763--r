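# Stain classification: patch extraction, weighted hue/value, the
# positive/negative rule, and the weak/moderate/strong classifier.

test_that("patch extraction crops, reflects at borders, and is deterministic", {
  set.seed(4)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  centre <- extract_patch(img, c(20, 20), size = 16)
  expect_equal(centre, img[13:28, 13:28, ])
  corner <- extract_patch(img, c(0, 0), size = 16)
  expect_equal(dim(corner), c(16, 16, 3))
  expect_false(anyNA(corner))
  # reflection about the first row/column: offsets -1, -2 mirror +1, +2
  expect_equal(corner[8, 7, ], img[2, 3, ])
  expect_equal(corner[9, 9, ], img[1, 1, ])
  expect_identical(extract_patch(img, c(0, 0), 16),
                   extract_patch(img, c(0, 0), 16))
  expect_error(extract_patch(img, c(100, 0)), "inside the image")
})

test_that("weighted hue/value equals the brute-force per-pixel oracle", {
  set.seed(77)
  for (rep in 1:4) {
    block <- array(runif(32 * 32 * 3), c(32, 32, 3))
    got <- weighted_hsv(block)
    want <- brute_weighted_hsv(block)
    expect_equal(got$wH, want$wH, tolerance = 1e-9)
    expect_equal(got$wV, want$wV, tolerance = 1e-9)
  }
})

test_that("weighted averages respect constant fields, weighting, and symmetry", {
  col <- c(0.6, 0.45, 0.3)
  uniform <- array(rep(col, each = 32 * 32), c(32, 32, 3))
  hv <- grDevices::rgb2hsv(col[1], col[2], col[3], maxColorValue = 1)
  got <- weighted_hsv(uniform)
  expect_equal(got$wH, hv[1] * 255, tolerance = 1e-9)
  expect_equal(got$wV, hv[3] * 255, tolerance = 1e-9)

  # brown centre, blue periphery: weighting pulls wH toward the centre hue
  ns <- asNamespace("erallred")
  brown <- ns$hsv255_to_rgb(20, 0.5, 150)
  blue <- ns$hsv255_to_rgb(160, 0.5, 150)
  block <- array(rep(blue, each = 32 * 32), c(32, 32, 3))
  for (ch in 1:3) block[9:24, 9:24, ch] <- brown[ch]
  wh <- weighted_hsv(block)$wH
  unweighted <- mean(ns$rgb_to_hsv255(block)$h)
  expect_lt(wh, unweighted)

  mirrored <- block[, 32:1, , drop = FALSE]
  expect_equal(weighted_hsv(mirrored)$wH, wh, tolerance = 1e-9)
})

test_that("the positive/negative rule matches its direct restatement", {
  # spot checks at the stated thresholds
  expect_equal(classify_pn(list(wH = 160, wV = 30)), "P")  # dark overrides hue
  expect_equal(classify_pn(list(wH = 20, wV = 120)), "P")  # brown
  expect_equal(classify_pn(list(wH = 160, wV = 120)), "N") # blue, not dark
  # boundary convention: positive at wH = 40; negative at wV = 50, wH > 40
  expect_equal(classify_pn(list(wH = 40, wV = 120)), "P")
  expect_equal(classify_pn(list(wH = 41, wV = 50)), "N")

  restatement <- function(wH, wV) {
    if (wV < 50) return("P")
    if (wH > 40) "N" else "P"
  }
  grid <- expand.grid(wH = seq(0, 255, by = 1), wV = seq(0, 255, by = 1))
  got <- character(nrow(grid))
  want <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    got[k] <- classify_pn(list(wH = grid$wH[k], wV = grid$wV[k]))
    want[k] <- restatement(grid$wH[k], grid$wV[k])
  }
  expect_identical(got, want)
})

test_that("classifier training validates inputs", {
  expect_error(wms_config(epochs = 0), "epochs")
  p <- generate_patchset(3, seed = 1)
  keep <- p$label %in% c("W", "M")
  expect_error(
    train_wms(p$x[, , , keep, drop = FALSE], p$label[keep],
              cfg = wms_config(epochs = 1)),
    "must be present"
  )
  expect_error(
    train_wms(p$x[, , , keep, drop = FALSE], c("W", "M", "X", "W", "M", "X"),
              cfg = wms_config(epochs = 1)),
    "labels"
  )
})

test_that("the trained classifier separates the three staining strengths", {
  wms <- shared_wms()
  expect_gte(wms$val_accuracy, 0.85)
  fresh <- generate_patchset(25, seed = 321)
  keep <- which(fresh$label %in% c("W", "M", "S"))
  pred <- vapply(keep, function(i) classify_wms(wms, fresh$x[, , , i]),
                 character(1))
  expect_gte(mean(pred == fresh$label[keep]), 0.85)
  # strong synthetic oracle cases: darkest patches are strong, palest weak
  s_idx <- which(fresh$label == "S")[1:5]
  w_idx <- which(fresh$label == "W")[1:5]
  expect_true(all(vapply(s_idx, function(i)
    classify_wms(wms, fresh$x[, , , i]), character(1)) == "S"))
  expect_true(all(vapply(w_idx, function(i)
    classify_wms(wms, fresh$x[, , , i]), character(1)) == "W"))
})

test_that("class posteriors are a proper distribution and stable", {
  wms <- shared_wms()
  p <- generate_patchset(2, seed = 9)
  for (i in seq_along(p$label)) {
    post <- wms_posterior(wms, p$x[, , , i])
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(post >= 0))
  }
  expect_identical(classify_wms(wms, p$x[, , , 1]),
                   classify_wms(wms, p$x[, , , 1]))
})

test_that("shuffled labels leave held-out accuracy at chance level", {
  p <- generate_patchset(60, seed = 47)
  keep <- which(p$label %in% c("W", "M", "S"))
  set.seed(13)
  shuffled <- sample(p$label[keep])
  m <- train_wms(p$x[, , , keep, drop = FALSE], shuffled,
                 cfg = wms_config(epochs = 8, seed = 3))
  # large held-out set keeps the chance-level estimate well inside the band
  fresh <- generate_patchset(250, seed = 48)
  fk <- which(fresh$label %in% c("W", "M", "S"))
  pred <- vapply(fk, function(i) classify_wms(m, fresh$x[, , , i]),
                 character(1))
  expect_lt(abs(mean(pred == fresh$label[fk]) - 1 / 3), 0.05)
})

test_that("training is reproducible for a fixed seed", {
  p <- generate_patchset(8, seed = 15)
  cfg <- wms_config(epochs = 2, seed = 44)
  a <- train_wms(p, cfg = cfg)
  b <- train_wms(p, cfg = cfg)
  expect_identical(a$history, b$history)
})

test_that("cell classification preserves order and short-circuits negatives", {
  sc <- generate_scene(scene_spec(width = 160, height = 160,
                                  n_cells = c(N = 6), seed = 88))
  empty <- classify_cells(sc$image, sc$truth[0, c("x", "y")])
  expect_equal(nrow(empty), 0)
  # an all-negative field needs no trained model at all
  res <- classify_cells(sc$image, sc$truth[, c("x", "y")], wms_model = NULL)
  expect_equal(res$label, rep("N", 6))
  expect_equal(res$x, sc$truth$x)
})

test_that("matched cells receive their ground-truth class end to end", {
  det <- shared_detector()
  wms <- shared_wms()
  ok <- 0L; n <- 0L
  for (sc in benchmark_scenes()[1:2]) {
    cells <- extract_cells(predict_score_map(det, sc$image))
    cells <- classify_cells(sc$image, cells, wms_model = wms)
    m <- match_detections(cells, sc$truth, tol = 16)
    ok <- ok + sum(cells$label[m$pairs$pred] == sc$truth$label[m$pairs$truth])
    n <- n + m$tp
  }
  expect_gte(n, 100)
  expect_gte(ok / n, 0.90)
})
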