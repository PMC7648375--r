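#' Round half away from zero
#'
#' Cohort tables in this field round 0.5 up (so 69/188 of patients -> 37%,
#' not the banker's-rounding 36.7 -> 37 vs 36). Base R `round()` rounds half
#' to even, so the convention is implemented explicitly.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(100 * 49 / 188, 1)  # 26.1
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

score_labels <- function() {
  c("no_risk", "low_risk", "medium_risk", "high_risk", "full_risk")
}

score_label <- function(points) {
  # points beyond 4 (the 5-item scale) keep the top label
  score_labels()[pmin(points, 4L) + 1L]
}

item_names <- function() {
  c("recent_fall", "confusion", "impaired_balance", "dizziness_drowsiness")
}

#' Admission fall-risk items
#'
#' The four binary items nurses assess on admission: evidence of a fall
#' within the month prior; confusion, lack of risk perception or
#' restlessness; impaired balance or gait disturbance; occurrence of
#' dizziness and drowsiness. Each item contributes one point.
#'
#' @param recent_fall,confusion,impaired_balance,dizziness_drowsiness
#'   Single logical values. A missing (`NA`) item is an error, not a zero:
#'   silent under-scoring is exactly the failure mode a screening tool must
#'   avoid.
#' @return Named logical vector of length 4.
#' @examples
#' admission_items(recent_fall = TRUE, confusion = FALSE,
#'                 impaired_balance = TRUE, dizziness_drowsiness = FALSE)
#' @export
admission_items <- function(recent_fall, confusion, impaired_balance,
                            dizziness_drowsiness) {
  items <- c(recent_fall = recent_fall, confusion = confusion,
             impaired_balance = impaired_balance,
             dizziness_drowsiness = dizziness_drowsiness)
  validate_items(items)
  items
}

validate_items <- function(items) {
  if (!all(item_names() %in% names(items))) {
    stop(frids_error(sprintf("missing admission item(s): %s",
                             paste(setdiff(item_names(), names(items)),
                                   collapse = ", ")),
                     "frids_validation_error"))
  }
  items <- items[item_names()]
  if (anyNA(items) || !is.logical(items)) {
    bad <- item_names()[is.na(items) | !is.logical(items)]
    stop(frids_error(sprintf("admission item(s) missing or non-logical: %s",
                             paste(bad, collapse = ", ")),
                     "frids_validation_error"))
  }
  invisible(items)
}

#' The routine 4-item admission fall-risk score
#'
#' One point per positive item; the total maps to a risk label: 0 no risk,
#' 1 low, 2 medium, 3 high, 4 full risk.
#'
#' @param items Named logical vector from [admission_items()] (or any named
#'   logical vector carrying the four item names).
#' @return One-row tibble of class `frids_score`: `points`, `max_points`
#'   (4), `label`, `medication_item` (`NA`, not part of the base score).
#' @examples
#' base_score(admission_items(TRUE, FALSE, TRUE, FALSE))
#' @export
base_score <- function(items) {
  items <- validate_items(items)
  points <- sum(items)
  out <- tibble::tibble(points = as.integer(points), max_points = 4L,
                        label = score_label(points),
                        medication_item = NA)
  class(out) <- c("frids_score", class(out))
  out
}

#' The medication-aware 5-item extended score
#'
#' Adds a fifth item to the admission score: exposure to high fall-risk
#' (category A) medication. The item scores one point when the patient uses
#' at least `threshold` category-A medicines. The threshold defaults to 1 and
#' is configurable because concomitant FRID use is common (the study cohort
#' averaged 3.8 concurrent category-A medicines) and stricter cutoffs are a
#' natural subject for follow-up calibration. Points 0-4 keep the base
#' labels; 5 points is full risk.
#'
#' @param items Named logical vector from [admission_items()].
#' @param medications Character vector of ingredient names and/or ATC codes;
#'   empty is valid (medication item false). Every entry must resolve in
#'   `kb`; unknowns raise a lookup error listing them.
#' @param kb A [frid_kb()].
#' @param threshold Minimum count of category-A medicines that triggers the
#'   item (integer >= 1).
#' @return One-row tibble of class `frids_score`: `points`, `max_points`
#'   (5), `label`, `medication_item` (logical).
#' @examples
#' kb <- frid_knowledge_base()
#' extended_score(admission_items(TRUE, TRUE, TRUE, FALSE),
#'                c("metoprolol", "quetiapine"), kb)
#' @export
extended_score <- function(items, medications, kb, threshold = 1L) {
  stopifnot(inherits(kb, "frid_kb"))
  if (threshold < 1) {
    stop(frids_error("threshold must be >= 1", "frids_validation_error"))
  }
  base <- base_score(items)
  n_a <- if (length(medications) == 0) {
    0L
  } else {
    profile_medications(medications, kb)$count_A
  }
  med_item <- n_a >= threshold
  points <- base$points + as.integer(med_item)
  out <- tibble::tibble(points = points, max_points = 5L,
                        label = score_label(points),
                        medication_item = med_item)
  class(out) <- c("frids_score", class(out))
  out
}

#' Distribution of fall-risk scores in a cohort
#'
#' @param scores Tibble of score rows (from [base_score()] /
#'   [extended_score()], stacked with `rbind`/`dplyr::bind_rows`), or an
#'   integer vector of points with `max_points` given explicitly. Mixing
#'   score scales (different `max_points`) is an error.
#' @param max_points Scale maximum when `scores` is a bare vector.
#' @return Tibble with one row per attainable score 0..max: `points`,
#'   `label`, `n`, `pct` (integer percentage, round half up). The attribute
#'   `share_high` holds the integer percentage of patients scoring >= 3
#'   ("at least high fall risk"), and `n_total` the cohort size.
#' @examples
#' d <- score_distribution(rep(0:4, c(5, 17, 66, 69, 31)), max_points = 4)
#' d
#' attr(d, "share_high")
#' @export
score_distribution <- function(scores, max_points = NULL) {
  if (is.data.frame(scores)) {
    if (nrow(scores) == 0) {
      stop(frids_error("empty score list", "frids_validation_error"))
    }
    if (length(unique(scores$max_points)) > 1) {
      stop(frids_error("mixed score scales (max_points differ)",
                       "frids_validation_error"))
    }
    max_points <- scores$max_points[1]
    points <- scores$points
  } else {
    if (length(scores) == 0) {
      stop(frids_error("empty score list", "frids_validation_error"))
    }
    if (is.null(max_points)) {
      stop(frids_error("max_points required for a bare points vector",
                       "frids_validation_error"))
    }
    points <- as.integer(scores)
  }
  if (any(points < 0 | points > max_points)) {
    stop(frids_error("points outside 0..max_points", "frids_validation_error"))
  }
  n_total <- length(points)
  counts <- tabulate(points + 1L, nbins = max_points + 1L)
  out <- tibble::tibble(points = 0:max_points,
                        label = score_label(0:max_points),
                        n = counts,
                        pct = round_half_up(100 * counts / n_total))
  attr(out, "share_high") <- round_half_up(100 * sum(points >= 3) / n_total)
  attr(out, "n_total") <- n_total
  out
}
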