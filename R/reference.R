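#' Published admission-score distribution of the study cohort
#'
#' The admission-score distribution of the 188 fall-experienced patients the
#' packaged knowledge base was derived from: scores 0 to 4 with counts
#' 5, 17, 66, 69 and 31. Used as the default calibration target for the
#' simulator and by the reference-cohort reconstruction.
#'
#' @return Named integer vector, names `"0"`..`"4"`.
#' @export
study_score_counts <- function() {
  c("0" = 5L, "1" = 17L, "2" = 66L, "3" = 69L, "4" = 31L)
}

# published cohort marginals used by the reconstruction and the simulator
study_marginals <- function() {
  list(n_patients = 188L, n_hospital = 128L, n_nursing = 60L,
       n_male_hospital = 67L, n_male_nursing = 18L,
       n_medicaments = 1748L, n_A = 710L, n_B = 331L, n_C = 707L,
       age = list(mean = 79, min = 60, max = 97),
       meds = list(mean = 9.3, min = 2, max = 17),
       mmse = list(mean = 21.7, min = 5, max = 30),
       los_hospital = list(mean = 15.8, min = 1, max = 56))
}

#' Reconstruct a cohort consistent with the published study tables
#'
#' Patient-level data for the study cohort are not deposited, but its
#' published aggregates pin down a cohort exactly consistent with them:
#' per-ingredient user counts for the 102 category-A substances, total
#' moderate-risk (331) and no-risk (707) medicament occurrences spread over
#' the synthetic B/C pools, the admission-score distribution, and the
#' setting/sex splits. This function builds such a cohort
#' deterministically — no randomness — by dealing each ingredient's
#' occurrences round-robin across the 188 patients, so each ingredient's
#' users are distinct patients and every patient carries 9 or 10
#' medicaments (within the published 2-17 range).
#'
#' Ages, lengths of stay and MMSE values cycle through fixed in-range
#' sequences: they make the cohort pass validation and are NOT calibrated
#' to the published means (use [generate_cohort()] for that). Aggregates
#' that depend on the joint patient-by-drug allocation — e.g. the
#' per-patient minimum/maximum/median category-A count — are likewise
#' properties of this reconstruction, not of the study.
#'
#' @param kb A [frid_kb()]; must be [reference_knowledge_base()] or a
#'   superset of it.
#' @return A cohort tibble of 188 patients.
#' @examples
#' coh <- reference_cohort()
#' nrow(coh)
#' @export
reference_cohort <- function(kb = reference_knowledge_base()) {
  m <- study_marginals()
  n <- m$n_patients

  # medicament occurrences: Table-6 user counts for A; B/C totals spread as
  # evenly as possible over the synthetic pools
  a <- frid_knowledge_base()$records
  occ_a <- rep(a$ingredient, a$users_n)
  occ_b <- rep(sprintf("synthetic_moderate_%02d", 1:29),
               spread_total(m$n_B, 29))
  occ_c <- rep(sprintf("synthetic_norisk_%02d", 1:85),
               spread_total(m$n_C, 85))
  occ <- c(occ_a, occ_b, occ_c)
  patient_of <- ((seq_along(occ) - 1L) %% n) + 1L
  meds <- split(occ, patient_of)

  # admission items realizing the published score distribution
  counts <- study_score_counts()
  scores <- rep(0:4, counts)
  items <- score_item_matrix(scores)

  setting <- rep(c("hospital", "nursing_home"), c(m$n_hospital, m$n_nursing))
  sex <- c(rep(c("male", "female"),
              c(m$n_male_hospital, m$n_hospital - m$n_male_hospital)),
           rep(c("male", "female"),
               c(m$n_male_nursing, m$n_nursing - m$n_male_nursing)))
  age <- rep_len(m$age$min:m$age$max, n)
  los <- ifelse(setting == "hospital",
                as.character(rep_len(m$los_hospital$min:m$los_hospital$max,
                                     n)),
                "permanent")
  mmse <- ifelse(setting == "hospital",
                 rep_len(m$mmse$min:m$mmse$max, n), NA_integer_)

  as_cohort(tibble::tibble(
    id = sprintf("p%03d", seq_len(n)),
    setting = setting, sex = sex, age = age,
    length_of_stay = los, mmse = as.integer(mmse),
    recent_fall = items[, 1], confusion = items[, 2],
    impaired_balance = items[, 3], dizziness_drowsiness = items[, 4],
    medications = unname(meds[as.character(seq_len(n))])))
}

# split `total` into `k` near-equal integer parts
spread_total <- function(total, k) {
  base <- total %/% k
  rep(base, k) + c(rep(1L, total %% k), rep(0L, k - total %% k))
}

# deterministic item combinations realizing given per-patient scores,
# cycling through the combinations of each weight
score_item_matrix <- function(scores) {
  combos <- lapply(0:4, function(s) utils::combn(4, s, simplify = FALSE))
  counter <- integer(5)
  t(vapply(scores, function(s) {
    counter[s + 1L] <<- counter[s + 1L] + 1L
    set <- combos[[s + 1L]]
    pick <- set[[((counter[s + 1L] - 1L) %% length(set)) + 1L]]
    out <- rep(FALSE, 4)
    out[pick] <- TRUE
    out
  }, logical(4)))
}
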