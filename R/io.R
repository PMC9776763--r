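# Pipeline configuration and report serialisation shared by the CLI and
# the programmatic interface.  All constants used by the pipeline surface
# here in one place.

config_defaults <- function() {
  list(
    cell_radius = 32,
    score_threshold = 0.2,
    min_region_area = 240,
    area_rule = "min",
    detection_patch_size = 64,
    patch_size = 32,
    hue_threshold = 40,
    value_threshold = 50,
    field_size = 256,
    match_tolerance = 16,
    treatment_cutoff = 3,
    seed = 1L,
    detector_model = NULL,
    wms_model = NULL
  )
}

validate_config <- function(cfg) {
  if (cfg$score_threshold <= 0 || cfg$score_threshold >= 1) {
    stop("invalid config: score_threshold must be in (0, 1)")
  }
  if (cfg$min_region_area <= 0) stop("invalid config: min_region_area <= 0")
  if (!cfg$area_rule %in% c("min", "max")) {
    stop("invalid config: area_rule must be 'min' or 'max'")
  }
  if (cfg$hue_threshold < 0 || cfg$hue_threshold >= 256 ||
      cfg$value_threshold < 0 || cfg$value_threshold > 255) {
    stop("invalid config: PN thresholds must be on the 0-255 scale")
  }
  if (cfg$match_tolerance <= 0) stop("invalid config: match_tolerance <= 0")
  if (cfg$cell_radius <= 0) stop("invalid config: cell_radius <= 0")
  cfg
}

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, fills unset keys with the
#' package defaults (score threshold 0.2, minimum region area 240, PN
#' thresholds 40/50, patch sizes 32/64, treatment cut-off 3), validates
#' bounds and rejects unknown keys.  An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  structure(validate_config(cfg), class = "pipeline_config")
}

#' @rdname load_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write / read a slide report
#'
#' Reports serialise a slide's class counts, ER percentage, Allred
#' components and recommendation, together with provenance (package
#' version, timestamp), as JSON.  The round trip is lossless: scores are
#' integers, proportions carry four decimals.  On read the Allred
#' invariants are enforced (a stored score of 1, or a proportion/intensity
#' pair that does not add up, is rejected); a version mismatch only warns.
#'
#' @param report A `slide_report` from [run_slide()], or a list with
#'   elements `summary` and `allred`.
#' @param path JSON file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the report list.
#' @export
write_report <- function(report, path) {
  summ <- report$summary
  res <- report$allred
  out <- list(
    counts = list(N = summ$N, W = summ$W, M = summ$M, S = summ$S),
    total = summ$total,
    er_pct = round(summ$er_pct, 4),
    pscore = res$pscore, iscore = res$iscore, score = res$score,
    actionable = res$actionable,
    low_positive = res$low_positive,
    provenance = list(
      package = "erallred",
      version = as.character(utils::packageVersion("erallred")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- tryCatch(rep$provenance$version, error = function(e) NULL)
  cur <- as.character(utils::packageVersion("erallred"))
  if (!is.null(ver) && !identical(ver, cur)) {
    warning("report written by erallred ", ver, ", reading with ", cur)
  }
  if (!is.null(rep$score)) {
    if (rep$score == 1 || !rep$score %in% c(0, 2:8)) {
      stop("corrupt report: Allred score ", rep$score, " is impossible")
    }
    if (!is.null(rep$pscore) && !is.null(rep$iscore) &&
        rep$pscore + rep$iscore != rep$score) {
      stop("corrupt report: pscore + iscore != score")
    }
  }
  rep
}

#' Save / load a trained model
#'
#' Models are self-describing: the file carries the layer architecture,
#' weights, the owning class (`cell_detector` or `wms_model`) and the
#' training configuration, so a loaded model is immediately usable for
#' prediction.
#'
#' @param model A `cell_detector` or `wms_model`.
#' @param path Output file path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("cell_detector", "wms_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("cell_detector", "wms_model"))) {
    stop("file does not contain an erallred model: ", path)
  }
  model
}
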