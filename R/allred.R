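# Allred scoring: converts per-slide stain-class composition into a
# proportion score (0-5), an intensity score (0-3, from the majority
# positive class), their sum (the Allred score, in {0, 2..8}; 1 is not a
# possible outcome) and a hormonal-therapy recommendation (score >= 3).

#' Allred proportion score
#'
#' Bins the percentage of positively stained cells into the six proportion
#' scores.  Bin edges are real-valued half-open intervals:
#' `0 -> 0`, `(0, 1) -> 1`, `[1, 10] -> 2`, `(10, 33] -> 3`,
#' `(33, 66] -> 4`, `(66, 100] -> 5`.
#'
#' @param p Percentage of positive cells, in `[0, 100]`. Vectorised.
#' @return Integer score(s) in `0..5`.
#' @export
proportion_score <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 100)) {
    stop("p must be a percentage in [0, 100]")
  }
  ifelse(p == 0, 0L,
  ifelse(p < 1, 1L,
  ifelse(p <= 10, 2L,
  ifelse(p <= 33, 3L,
  ifelse(p <= 66, 4L, 5L)))))
}

#' Allred intensity score
#'
#' The intensity score is taken from the majority positive class: 3 if
#' strong cells dominate, 2 if moderate, 1 if weak, and 0 only when there
#' are no positive cells at all.  Exact ties break toward the stronger
#' class.  Arguments may be counts or proportions; only their ordering
#' matters.
#'
#' @param strong,moderate,weak Non-negative counts or proportions.
#' @return Integer score in `0..3`.
#' @export
intensity_score <- function(strong, moderate, weak) {
  v <- c(strong, moderate, weak)
  if (any(is.na(v)) || any(v < 0)) stop("class amounts must be >= 0")
  if (all(v == 0)) return(0L)
  c(3L, 2L, 1L)[which.max(v)] # ties resolve toward the stronger class
}

#' Summarise a slide's stain-class composition
#'
#' @param N,W,M,S Per-class cell counts (or proportions) for negative,
#'   weak, moderate and strong cells.
#' @param er_pct Optional ER status (% positive of all cells); computed
#'   from the class amounts when omitted.  Supplying it explicitly allows
#'   scoring published summaries whose printed percentage and class
#'   proportions were rounded independently.
#' @return A `slide_summary` tibble with one row: class amounts, `total`
#'   and `er_pct`.
#' @export
slide_summary <- function(N = 0, W = 0, M = 0, S = 0, er_pct = NULL) {
  v <- c(N = N, W = W, M = M, S = S)
  if (any(is.na(v)) || any(v < 0)) stop("class amounts must be >= 0")
  total <- sum(v)
  if (is.null(er_pct)) {
    if (total == 0) {
      er_pct <- NA_real_
    } else {
      er_pct <- 100 * (W + M + S) / total
    }
  }
  structure(tibble::tibble(N = N, W = W, M = M, S = S, total = total,
                           er_pct = er_pct),
            class = c("slide_summary", class(tibble::tibble())))
}

#' Allred score of a slide
#'
#' Adds the proportion score for the slide's positive-cell percentage and
#' the intensity score of its majority positive class, and flags whether
#' the score is actionable (supports hormonal therapy, score >= 3).
#' Slides with a very small positive fraction (below 0.1%) are flagged in
#' `low_positive` since scores there hinge on a handful of detections.
#'
#' @param summary A [slide_summary()] (or any one-row data frame with
#'   columns `W`, `M`, `S`, `er_pct` and optionally `total`).
#' @return An `allred_result`: list with `pscore`, `iscore`, `score`,
#'   `actionable`, `er_pct` and `low_positive`.
#' @examples
#' allred(slide_summary(N = 524, W = 430, M = 28, S = 17))
#' @export
allred <- function(summary) {
  stopifnot(is.data.frame(summary), nrow(summary) == 1)
  if (!is.null(summary$total) && summary$total == 0) {
    stop("unscorable slide: total cell count is 0")
  }
  p <- summary$er_pct
  if (is.null(p) || is.na(p)) stop("summary must carry er_pct")
  ps <- proportion_score(p)
  is_ <- if (ps == 0L) 0L else {
    intensity_score(summary$S, summary$M, summary$W)
  }
  if (ps > 0L && is_ == 0L) {
    # positive percentage with no positive class amounts: treat the
    # majority rule as weak-dominant (can only arise from inconsistent
    # hand-entered summaries)
    is_ <- 1L
  }
  score <- ps + is_
  structure(list(pscore = ps, iscore = is_, score = score,
                 actionable = treatment(score), er_pct = p,
                 low_positive = p > 0 && p < 0.1),
            class = "allred_result")
}

#' Hormonal-treatment recommendation from an Allred score
#'
#' Scores of 0 and 2 are negative (not actionable); scores of 3 to 8 are
#' positive (hormonal therapy recommended).  A score of 1 is impossible
#' under the scoring rules and is rejected.
#'
#' @param score Allred score in `{0, 2..8}`. Vectorised.
#' @return Logical: `TRUE` when hormonal therapy is recommended.
#' @export
treatment <- function(score) {
  if (any(is.na(score)) || any(score == 1) ||
      any(!score %in% c(0, 2:8))) {
    stop("Allred score must be in {0, 2..8} (a score of 1 cannot occur)")
  }
  score >= 3
}

#' @export
print.allred_result <- function(x, ...) {
  cat("<allred_result> proportion ", x$pscore, " + intensity ", x$iscore,
      " = Allred ", x$score, " (ER ", signif(x$er_pct, 4), "%); ",
      if (x$actionable) "hormonal therapy recommended" else "not actionable",
      if (x$low_positive) " [flag: <0.1% positive]" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.allred_result <- function(x, ...) {
  tibble::tibble(pscore = x$pscore, iscore = x$iscore, score = x$score,
                 actionable = x$actionable, er_pct = x$er_pct,
                 low_positive = x$low_positive)
}
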