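# Cell detection: score targets, analytic extraction fixtures, detector
# training and whole-image prediction.

test_that("score targets form unit cones clipped at radius R", {
  tg <- build_score_target(tibble::tibble(x = 50, y = 60), c(128, 128), R = 32)
  expect_equal(tg[61, 51], 1.0)            # apex: d = 0
  expect_equal(tg[61, 51 + 16], 0.5)       # d = 16 at R = 32
  expect_equal(tg[61, 51 + 33], 0.0)       # beyond R: clipped
  expect_equal(tg[61 - 32, 51], 0.0)       # d = R exactly
  empty <- build_score_target(tibble::tibble(x = numeric(0), y = numeric(0)),
                              c(40, 40))
  expect_true(all(empty == 0))
  expect_error(build_score_target(tibble::tibble(x = 500, y = 5), c(64, 64)),
               "inside the image")
})

test_that("extraction recovers the apex of an ideal cone within 1 px", {
  tg <- build_score_target(tibble::tibble(x = 50, y = 60), c(128, 128))
  cells <- extract_cells(tg)
  expect_equal(nrow(cells), 1)
  expect_lt(abs(cells$x - 50) + abs(cells$y - 60), 1)
  expect_gt(cells$area, 240)
})

test_that("two merged cones 40 px apart split into two cells near the apexes", {
  tg <- build_score_target(tibble::tibble(x = c(40, 80), y = c(60, 60)),
                           c(128, 128))
  # merged at threshold 0.2 (disk radius 0.8 R = 25.6 each)
  cells <- extract_cells(tg)
  expect_equal(nrow(cells), 2)
  d1 <- sqrt((cells$x - 40)^2 + (cells$y - 60)^2)
  d2 <- sqrt((cells$x - 80)^2 + (cells$y - 60)^2)
  expect_lt(min(d1), 2)
  expect_lt(min(d2), 2)
})

test_that("extraction is the inverse of target building for separated cells", {
  # non-overlapping centroids (pairwise distance > 2R) must be recovered
  # exactly; the brute-force oracle here is the input list itself
  set.seed(12)
  pts <- tibble::tibble(x = c(40, 120, 200, 60, 180, 130),
                        y = c(40, 50, 60, 160, 170, 200))
  cells <- extract_cells(build_score_target(pts, c(250, 250)))
  expect_equal(nrow(cells), nrow(pts))
  m <- match_detections(cells, pts, tol = 1.5)
  expect_equal(m$tp, nrow(pts))
  expect_equal(m$fp + m$fn, 0)
})

test_that("extraction is deterministic and ordered by y then x", {
  tg <- build_score_target(tibble::tibble(x = c(40, 80), y = c(80, 40)),
                           c(128, 128))
  a <- extract_cells(tg)
  b <- extract_cells(tg)
  expect_identical(a, b)
  expect_equal(a$y, sort(a$y))
  zero <- build_score_target(tibble::tibble(x = numeric(0), y = numeric(0)),
                             c(64, 64))
  expect_equal(nrow(extract_cells(zero)), 0)
})

test_that("raising the score threshold never increases the cell count", {
  sm <- predict_score_map(shared_detector(), benchmark_scenes()[[1]]$image)
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(thr) {
    nrow(extract_cells(sm, detection_params(score_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("training requires positive windows and a sane budget", {
  expect_error(detector_config(epochs = 0), "epochs")
  empty_scene <- generate_scene(scene_spec(width = 96, height = 96,
                                           n_cells = c(N = 0), seed = 1))
  expect_error(train_detector(list(empty_scene),
                              cfg = detector_config(epochs = 1)),
               "no positive training windows")
})

test_that("the trained regressor beats the constant predictor", {
  det <- shared_detector()
  expect_lt(det$val_mse, det$val_baseline)
  # training loss decreased over epochs
  expect_lt(tail(det$history, 1), det$history[1])
})

test_that("background-only fields score below threshold almost everywhere", {
  bg <- generate_scene(scene_spec(width = 128, height = 128,
                                  n_cells = c(N = 0), seed = 55))
  sm <- predict_score_map(shared_detector(), bg$image)
  expect_gte(mean(sm < 0.2), 0.99)
})

test_that("an isolated nucleus yields one peak near the true centroid", {
  sc <- generate_scene(scene_spec(width = 128, height = 128,
                                  n_cells = c(M = 1), seed = 66))
  sm <- predict_score_map(shared_detector(), sc$image)
  cells <- extract_cells(sm)
  expect_equal(nrow(cells), 1)
  expect_lt(sqrt((cells$x - sc$truth$x)^2 + (cells$y - sc$truth$y)^2), 8)
})

test_that("a constant-colour image maps to a spatially constant interior", {
  img <- array(0.7, c(64, 64, 3))
  sm <- predict_score_map(shared_detector(), img)
  interior <- sm[20:45, 20:45]
  expect_lt(max(interior) - min(interior), 1e-8)
})

test_that("prediction rejects images below the receptive field", {
  expect_error(predict_score_map(shared_detector(), array(0.5, c(16, 16, 3))),
               "receptive field")
})

test_that("detector training is reproducible for a fixed seed", {
  sc <- list(generate_scene(scene_spec(width = 128, height = 128,
                                       n_cells = c(N = 3, S = 2), seed = 8)))
  cfg <- detector_config(epochs = 2, seed = 99)
  a <- train_detector(sc, cfg = cfg)
  b <- train_detector(sc, cfg = cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$net$layers, b$net$layers)
})
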