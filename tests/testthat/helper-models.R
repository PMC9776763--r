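# Shared fixtures.  Training is the expensive step of the suite, so the
# detector, the staining classifier and the benchmark scenes are built once
# per session (fixed seeds chosen up front; reduced epoch budgets).

.fixture_cache <- new.env(parent = emptyenv())

training_scenes <- function() {
  if (is.null(.fixture_cache$training_scenes)) {
    .fixture_cache$training_scenes <- lapply(1:3, function(i) {
      generate_scene(scene_spec(
        width = 256, height = 256,
        n_cells = c(N = 15, W = 7, M = 7, S = 7), seed = 100 + i
      ))
    })
  }
  .fixture_cache$training_scenes
}

shared_detector <- function() {
  if (is.null(.fixture_cache$detector)) {
    .fixture_cache$detector <- train_detector(
      training_scenes(),
      cfg = detector_config(epochs = 12, seed = 5)
    )
  }
  .fixture_cache$detector
}

shared_patchset <- function() {
  if (is.null(.fixture_cache$patchset)) {
    .fixture_cache$patchset <- generate_patchset(130, seed = 11)
  }
  .fixture_cache$patchset
}

shared_wms <- function() {
  if (is.null(.fixture_cache$wms)) {
    .fixture_cache$wms <- train_wms(
      shared_patchset(), cfg = wms_config(epochs = 15, seed = 5)
    )
  }
  .fixture_cache$wms
}

# Three held-out scenes with >= 200 nuclei in total, moderate density.
benchmark_scenes <- function() {
  if (is.null(.fixture_cache$benchmark_scenes)) {
    .fixture_cache$benchmark_scenes <- lapply(1:3, function(s) {
      generate_scene(scene_spec(
        width = 384, height = 384,
        n_cells = c(N = 30, W = 15, M = 15, S = 15), seed = 770 + s
      ))
    })
  }
  .fixture_cache$benchmark_scenes
}

f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}
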