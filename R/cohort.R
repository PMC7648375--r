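#' Assemble and validate a patient cohort
#'
#' A cohort is a tibble with one row per patient: `id`, `setting`
#' (`hospital` or `nursing_home`), `sex` (`male`/`female`), `age` (years,
#' >= 60 — the study population is older adults and younger ages are an
#' inclusion violation, not a quiet edge case), `length_of_stay` (days, or
#' the marker `"permanent"` for nursing-home residents), `mmse` (0-30 or
#' `NA`), the four admission items as logicals, and `medications` (a
#' list-column of character vectors naming ingredients and/or ATC codes;
#' empty vectors are valid).
#'
#' @param x Data frame with the columns above (`medications` may also be a
#'   character column of semicolon-separated entries).
#' @return A validated cohort tibble of class `frids_cohort`.
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("id", "setting", "sex", "age", "length_of_stay", "mmse",
            item_names(), "medications")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(frids_error(sprintf("cohort missing column(s): %s",
                             paste(miss, collapse = ", ")),
                     "frids_format_error"))
  }
  if (!is.list(x$medications)) {
    x$medications <- lapply(as.character(x$medications), split_medications)
  }
  x$id <- as.character(x$id)
  x$age <- as.integer(x$age)
  x$mmse <- suppressWarnings(as.integer(x$mmse))
  x$length_of_stay <- as.character(x$length_of_stay)
  for (it in item_names()) x[[it]] <- parse_binary(x[[it]], it)
  validate_cohort(x)
  x <- x[, need]
  class(x) <- c("frids_cohort", class(x))
  x
}

split_medications <- function(s) {
  if (is.na(s) || trimws(s) == "") return(character())
  trimws(strsplit(s, ";", fixed = TRUE)[[1]])
}

parse_binary <- function(v, name) {
  if (is.logical(v)) return(v)
  v <- trimws(as.character(v))
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true")] <- TRUE
  out[v %in% c("0", "FALSE", "false")] <- FALSE
  # an empty field is a missing item: flagged downstream, not a format error
  blank <- is.na(v) | v == ""
  if (any(is.na(out) & !blank)) {
    bad <- which(is.na(out) & !blank)
    stop(frids_error(sprintf("non-binary value '%s' for item %s (row %d)",
                             v[bad[1]], name, bad[1]),
                     "frids_format_error"))
  }
  out
}

validate_cohort <- function(x) {
  row_err <- function(rows, msg, class) {
    stop(frids_error(sprintf("%s (row %s)", msg,
                             paste(rows, collapse = ", ")), class))
  }
  bad <- which(!x$setting %in% c("hospital", "nursing_home"))
  if (length(bad)) row_err(bad, sprintf("unknown setting '%s'",
                                        x$setting[bad[1]]),
                           "frids_format_error")
  bad <- which(!x$sex %in% c("male", "female"))
  if (length(bad)) row_err(bad, sprintf("unknown sex '%s'", x$sex[bad[1]]),
                           "frids_format_error")
  bad <- which(is.na(x$age) | x$age < 60)
  if (length(bad)) row_err(bad, "age below the inclusion criterion (>= 60)",
                           "frids_inclusion_error")
  bad <- which(!is.na(x$mmse) & (x$mmse < 0 | x$mmse > 30))
  if (length(bad)) row_err(bad, "mmse outside 0..30",
                           "frids_validation_error")
  los_num <- suppressWarnings(as.numeric(x$length_of_stay))
  bad <- which(x$length_of_stay != "permanent" &
                 (is.na(los_num) | los_num <= 0 | los_num != floor(los_num)))
  if (length(bad)) row_err(bad, "length_of_stay must be a positive integer or 'permanent'",
                           "frids_format_error")
  for (it in item_names()) {
    bad <- which(is.na(x[[it]]))
    if (length(bad)) row_err(bad, sprintf("missing admission item %s", it),
                             "frids_validation_error")
  }
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' Expects the header `id,setting,sex,age,length_of_stay,mmse,recent_fall,
#' confusion,impaired_balance,dizziness_drowsiness,medications` with the
#' medication list semicolon-separated and `mmse` possibly empty. Validation
#' errors name the offending row.
#'
#' @param path CSV file path.
#' @return A cohort tibble (see [as_cohort()]); a header-only file yields an
#'   empty cohort.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop(frids_error(sprintf("no such file: %s", path), "frids_io_error"))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) {
    raw$medications <- character()
  }
  as_cohort(raw)
}

#' Write a patient cohort to CSV
#'
#' `read_cohort(write_cohort(cohort, path))` reproduces the cohort
#' field-for-field.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort[, setdiff(names(cohort), "medications")])
  for (it in item_names()) out[[it]] <- as.integer(out[[it]])
  out$medications <- vapply(cohort$medications, paste, "", collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Profile a medication list against the knowledge base
#'
#' Resolves each entry (exact ATC code first, then normalized ingredient
#' name), categorizes it, and counts medicines per risk level. Duplicate
#' entries count twice: the analysis counts medicaments in use, not distinct
#' substances.
#'
#' @param medications Character vector of ingredient names and/or ATC codes.
#' @param kb A [frid_kb()].
#' @param level_map Optional precomputed [risk_level_map()] (a cohort-level
#'   loop should compute it once).
#' @param resolver Optional precomputed resolver from [kb_resolver()] (a
#'   cohort-level loop should build it once).
#' @return A list: `count_A`, `count_B`, `count_C`, `n_medications`,
#'   `category_a` (resolved category-A ingredient names, ordered by
#'   knowledge-base user count then alphabetically).
#' @export
profile_medications <- function(medications, kb, level_map = NULL,
                                resolver = NULL) {
  if (length(medications) == 0) {
    return(list(count_A = 0L, count_B = 0L, count_C = 0L,
                n_medications = 0L, category_a = character()))
  }
  if (is.null(resolver)) resolver <- kb_resolver(kb, level_map)
  idx <- resolve_medication_keys(medications, resolver)
  key_ing <- resolver$ingredient[idx]
  key_level <- resolver$level[idx]
  a_sel <- key_level == "A"
  a_ing <- key_ing[a_sel]
  if (length(a_ing) > 0) {
    users <- resolver$users_n[idx][a_sel]
    a_ing <- a_ing[order(-replace(users, is.na(users), 0L), a_ing)]
  }
  list(count_A = sum(key_level == "A"),
       count_B = sum(key_level == "B"),
       count_C = sum(key_level == "C"),
       n_medications = length(medications),
       category_a = a_ing)
}

#' Build a medication-key resolver for a knowledge base
#'
#' Precomputes the ingredient-name and ATC-code indexes plus the per-record
#' risk level, so that repeated per-patient profiling does not re-categorize
#' the knowledge base. An ATC key shared by several records (misprinted
#' codes occur in published tables) resolves to the highest-risk record so a
#' medicament is never under-counted.
#'
#' @param kb A [frid_kb()].
#' @param level_map Optional precomputed [risk_level_map()].
#' @return An internal resolver object.
#' @export
kb_resolver <- function(kb, level_map = NULL) {
  if (is.null(level_map)) level_map <- risk_level_map(kb)
  level <- unname(level_map[kb$records$ingredient])
  # order records so the highest level comes first within a shared ATC code
  sev <- match(level, risk_levels())
  ord <- order(sev)
  atc_first <- ord[!duplicated(kb$records$atc_code[ord])]
  list(ingredient = kb$records$ingredient,
       atc_code = kb$records$atc_code,
       users_n = kb$records$users_n,
       level = level,
       by_atc = stats::setNames(atc_first, kb$records$atc_code[atc_first]))
}

resolve_medication_keys <- function(medications, resolver) {
  key <- trimws(medications)
  idx <- rep(NA_integer_, length(key))
  atc_shaped <- grepl(atc_pattern(), toupper(key))
  idx[atc_shaped] <- resolver$by_atc[toupper(key[atc_shaped])]
  rest <- is.na(idx)
  idx[rest] <- match(normalize_ingredient(key[rest]), resolver$ingredient)
  if (anyNA(idx)) {
    stop(frids_error(sprintf("unknown medication(s): %s",
                             paste(unique(medications[is.na(idx)]),
                                   collapse = ", ")),
                     "frids_lookup_error"))
  }
  idx
}

#' Per-patient FRID exposure profiles for a cohort
#'
#' @param cohort A cohort tibble.
#' @param kb A [frid_kb()].
#' @return Tibble with one row per patient: `id`, `count_A`, `count_B`,
#'   `count_C`, `n_medications`, `category_a` (list-column). The three
#'   counts partition the medication list for every patient.
#' @examples
#' kb <- reference_knowledge_base()
#' head(profile_cohort(reference_cohort(), kb))
#' @export
profile_cohort <- function(cohort, kb) {
  stopifnot(inherits(kb, "frid_kb"))
  res <- kb_resolver(kb)
  prof <- lapply(cohort$medications, profile_medications, kb = kb,
                 resolver = res)
  tibble::tibble(
    id = cohort$id,
    count_A = vapply(prof, `[[`, 1L, "count_A"),
    count_B = vapply(prof, `[[`, 1L, "count_B"),
    count_C = vapply(prof, `[[`, 1L, "count_C"),
    n_medications = vapply(prof, `[[`, 1L, "n_medications"),
    category_a = lapply(prof, `[[`, "category_a"))
}
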