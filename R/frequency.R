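#' SmPC adverse-effect frequency classes
#'
#' The Summary of Product Characteristics (SmPC) reports every adverse drug
#' effect (ADE) in one of five statutory frequency classes, plus "unknown"
#' when no frequency can be estimated. The classes are defined as proportions
#' of treated patients experiencing the effect.
#'
#' @return A tibble with one row per class: `label`, `lower_bound` and
#'   `upper_bound` (per-1 proportions; the upper bound is exclusive and absent
#'   for `very_common`, both bounds absent for `unknown`), and `rank` (1 =
#'   most frequent; `unknown` sorts last).
#' @examples
#' frequency_classes()
#' @export
frequency_classes <- function() {
  tibble::tibble(
    label = c("very_common", "common", "uncommon", "rare", "very_rare",
              "unknown"),
    lower_bound = c(1 / 10, 1 / 100, 1 / 1000, 1 / 10000, 0, NA_real_),
    upper_bound = c(NA_real_, 1 / 10, 1 / 100, 1 / 1000, 1 / 10000, NA_real_),
    rank = 1:6
  )
}

#' @rdname frequency_classes
#' @format NULL
#' @export
frequency_levels <- function() frequency_classes()$label

assert_frequency <- function(freq, arg = "frequency") {
  bad <- setdiff(unique(freq), frequency_levels())
  if (length(bad) > 0) {
    stop(sprintf("invalid %s label(s): %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(freq)
}

#' Map an SmPC frequency class to a fall-risk level
#'
#' The core categorization rule: an ADE documented as `very_common` or
#' `common` marks high fall risk (A), `uncommon` marks moderate risk (B), and
#' `rare` or `very_rare` marks no relevant risk (C). An `unknown` frequency
#' carries no evidence either way and maps to C on its own; at the drug level
#' it is surfaced as a flag rather than silently dropped (see
#' [categorize_drug()]).
#'
#' @param freq Character vector of frequency labels (see
#'   [frequency_levels()]).
#' @return Character vector of risk levels `"A"`, `"B"` or `"C"`, same length
#'   as `freq`.
#' @examples
#' risk_from_frequency(c("common", "uncommon", "very_rare", "unknown"))
#' @export
risk_from_frequency <- function(freq) {
  assert_frequency(freq)
  map <- c(very_common = "A", common = "A", uncommon = "B",
           rare = "C", very_rare = "C", unknown = "C")
  unname(map[freq])
}

#' @rdname risk_from_frequency
#' @details `risk_levels()` returns the three levels in decreasing severity;
#'   A (high) > B (moderate) > C (none).
#' @export
risk_levels <- function() c("A", "B", "C")
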