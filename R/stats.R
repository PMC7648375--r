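#' Cohort-level descriptive summary
#'
#' Reproduces the structure of a FRID cohort report: participant
#' characteristics, per-patient medication burden, risk-category shares at
#' two denominators, the category-A ATC roll-up and the top-FRID ranking.
#' Three denominators recur in this analysis and are easy to conflate, so
#' every output keeps its own explicit: medicament occurrences (a medicine
#' counted each time it appears in a patient list), distinct active
#' substances, and distinct users of an ingredient. Integer percentages
#' round half up; user percentages are reported to one decimal.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param kb A [frid_kb()] resolving every medication in the cohort.
#' @param top_k Number of rows in the top-FRID ranking.
#' @param by_setting If `TRUE`, adds a `by_setting` element with the
#'   medication tables stratified by care setting; the headline tables pool
#'   both settings (the widest coverage of medicines in use).
#' @return An object of class `frids_summary`: a list with elements
#'   `patients` (counts by setting and sex; age and medication-burden
#'   statistics), `medicaments` (A/B/C occurrence counts and percentages),
#'   `substances` (A/B/C distinct-substance counts and percentages),
#'   `per_patient_a` (mean/min/max/median category-A count),
#'   `rollup` (list of level 1-3 category-A roll-ups), `top_frids`,
#'   and `denominators`.
#' @examples
#' kb <- reference_knowledge_base()
#' summarize_cohort(reference_cohort(), kb)
#' @export
summarize_cohort <- function(cohort, kb, top_k = 10, by_setting = FALSE) {
  if (nrow(cohort) == 0) {
    stop(frids_error("empty cohort", "frids_validation_error"))
  }
  prof <- profile_cohort(cohort, kb)
  occ <- medicament_occurrences(cohort, kb)

  patients <- tibble::tibble(
    setting = c("hospital", "nursing_home", "total"),
    n = c(sum(cohort$setting == "hospital"),
          sum(cohort$setting == "nursing_home"), nrow(cohort)),
    n_male = c(sum(cohort$sex == "male" & cohort$setting == "hospital"),
               sum(cohort$sex == "male" & cohort$setting == "nursing_home"),
               sum(cohort$sex == "male")),
    n_female = c(sum(cohort$sex == "female" & cohort$setting == "hospital"),
                 sum(cohort$sex == "female" &
                       cohort$setting == "nursing_home"),
                 sum(cohort$sex == "female")))
  patients$pct_male <- round_half_up(100 * patients$n_male / patients$n)
  patients$pct_female <- round_half_up(100 * patients$n_female / patients$n)
  age <- list(mean = round_half_up(mean(cohort$age), 1),
              min = min(cohort$age), max = max(cohort$age),
              sd = stats::sd(cohort$age))
  meds_per_patient <- list(mean = round_half_up(mean(prof$n_medications), 1),
                           min = min(prof$n_medications),
                           max = max(prof$n_medications))

  medicaments <- category_share_table(occ$level, nrow(occ))
  sub_level <- occ$level[!duplicated(occ$ingredient)]
  substances <- category_share_table(sub_level, length(sub_level))

  structure(list(
    patients = patients, age = age, meds_per_patient = meds_per_patient,
    medicaments = medicaments, substances = substances,
    per_patient_a = per_patient_a_stats(cohort, kb, profiles = prof),
    rollup = lapply(stats::setNames(1:3, paste0("level", 1:3)),
                    function(l) atc_rollup(occ[occ$level == "A", ], l)),
    top_frids = top_frids(cohort, kb, k = top_k),
    by_setting = if (by_setting) {
      lapply(split(cohort, cohort$setting), summarize_cohort, kb = kb,
             top_k = top_k)
    },
    denominators = list(medicaments = nrow(occ),
                        substances = length(sub_level),
                        patients = nrow(cohort))),
    class = "frids_summary")
}

category_share_table <- function(levels_vec, denom) {
  n <- vapply(risk_levels(), function(l) sum(levels_vec == l), 1L)
  tibble::tibble(level = risk_levels(), n = unname(n),
                 share = unname(n) / denom,
                 pct = round_half_up(100 * unname(n) / denom))
}

# one row per medicament occurrence: patient id, resolved ingredient,
# atc_code, risk level
medicament_occurrences <- function(cohort, kb) {
  res <- kb_resolver(kb)
  idx_list <- lapply(cohort$medications, resolve_medication_keys, res)
  idx <- unlist(idx_list, use.names = FALSE)
  tibble::tibble(
    id = rep(cohort$id, lengths(idx_list)),
    ingredient = res$ingredient[idx],
    atc_code = res$atc_code[idx],
    level = res$level[idx])
}

#' @export
print.frids_summary <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' ATC roll-up of medicament occurrences
#'
#' Aggregates medicaments by Anatomical Therapeutic Chemical group:
#' level 1 is the anatomical main group (first letter), level 2 the
#' therapeutic subgroup (first three characters), level 3 the
#' pharmacological subgroup (first four characters). Percentages are
#' relative to the input size (e.g. the category-A medicaments being rolled
#' up), not the cohort.
#'
#' @param medicaments Tibble with columns `ingredient` and `atc_code`, one
#'   row per occurrence.
#' @param level Roll-up level, 1, 2 or 3.
#' @return Tibble `group`, `n`, `pct` (integer, round half up), sorted by
#'   `n` descending then group. Groups partition the input: `sum(n)` equals
#'   `nrow(medicaments)`.
#' @examples
#' kb <- reference_knowledge_base()
#' occ <- summarize_cohort(reference_cohort(), kb)$rollup$level1
#' @export
atc_rollup <- function(medicaments, level) {
  stopifnot(level %in% 1:3)
  atc <- toupper(trimws(medicaments$atc_code))
  bad <- atc[!grepl(atc_pattern(), atc)]
  if (length(bad) > 0) {
    stop(frids_error(sprintf("malformed ATC code(s): %s",
                             paste(unique(bad), collapse = ", ")),
                     "frids_format_error"))
  }
  width <- c(1L, 3L, 4L)[level]
  tab <- table(substr(atc, 1L, width))
  out <- tibble::tibble(group = names(tab), n = as.integer(tab),
                        pct = round_half_up(100 * as.integer(tab) /
                                              length(atc)))
  out[order(-out$n, out$group), ]
}

#' Rank the most-used category-A ingredients
#'
#' `users_n` counts distinct patients using the ingredient — a patient with
#' the same substance listed twice counts once — and `users_pct` is the
#' share of the whole cohort, to one decimal, round half up. Ingredients
#' used by nobody are excluded.
#'
#' @param cohort A cohort tibble.
#' @param kb A [frid_kb()].
#' @param k Number of rows to keep (`Inf` for all).
#' @return Tibble `ingredient`, `atc_code`, `drug_class`, `users_n`,
#'   `users_pct`, sorted by `users_n` descending, ties alphabetical.
#' @examples
#' kb <- reference_knowledge_base()
#' top_frids(reference_cohort(), kb, k = 3)
#' @export
top_frids <- function(cohort, kb, k = 10) {
  stopifnot(k >= 1)
  occ <- medicament_occurrences(cohort, kb)
  occ <- occ[occ$level == "A", ]
  occ <- dplyr::distinct(occ, .data$id, .data$ingredient,
                         .keep_all = TRUE)
  if (nrow(occ) == 0) {
    return(tibble::tibble(ingredient = character(), atc_code = character(),
                          drug_class = character(), users_n = integer(),
                          users_pct = double()))
  }
  users <- dplyr::count(occ, .data$ingredient, name = "users_n")
  users <- dplyr::left_join(
    users, dplyr::distinct(kb$records[, c("ingredient", "atc_code",
                                          "drug_class")]),
    by = "ingredient")
  users$users_pct <- round_half_up(100 * users$users_n / nrow(cohort), 1)
  users <- users[order(-users$users_n, users$ingredient), ]
  utils::head(users[, c("ingredient", "atc_code", "drug_class", "users_n",
                        "users_pct")], k)
}

#' Per-patient category-A burden statistics
#'
#' @param cohort A cohort tibble.
#' @param kb A [frid_kb()].
#' @param profiles Optional precomputed [profile_cohort()] result.
#' @return A list `mean` (one decimal, round half up), `min`, `max`,
#'   `median` of the per-patient count of category-A medicaments.
#' @export
per_patient_a_stats <- function(cohort, kb, profiles = NULL) {
  if (nrow(cohort) == 0) {
    stop(frids_error("empty cohort", "frids_validation_error"))
  }
  if (is.null(profiles)) profiles <- profile_cohort(cohort, kb)
  a <- profiles$count_A
  list(mean = round_half_up(mean(a), 1), min = min(a), max = max(a),
       median = stats::median(a))
}
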