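#' The fall-risk ADE vocabulary
#'
#' Fall risk is mediated by a small set of adverse-effect mechanisms:
#' sedation, orthostatic hypotension, syncope, dizziness, drowsiness, changes
#' in blood pressure and impaired balance, plus a direct "falls" listing that
#' some SmPCs carry. SmPCs name these mechanisms inconsistently (somnolence
#' vs drowsiness, vertigo vs dizziness, ...), so raw terms are resolved to
#' canonical mechanisms through a synonym map before categorization.
#'
#' @param extra_synonyms Optional named character vector of additional raw
#'   term -> canonical term mappings, e.g. `c("light-headedness" =
#'   "dizziness")`; entries override the defaults. Canonical targets must be
#'   members of the canonical set.
#' @return A list with `canonical` (character vector of the eight canonical
#'   terms) and `synonyms` (named character vector mapping raw, case-folded
#'   terms to canonical terms; every canonical term maps to itself).
#' @examples
#' v <- ade_vocabulary()
#' v$synonyms[["somnolence"]]
#' @export
ade_vocabulary <- function(extra_synonyms = NULL) {
  canonical <- c("sedation", "orthostatic_hypotension", "syncope",
                 "dizziness", "drowsiness", "blood_pressure_change",
                 "impaired_balance", "fall")
  synonyms <- c(
    stats::setNames(canonical, canonical),
    "orthostatic hypotension" = "orthostatic_hypotension",
    "postural hypotension"    = "orthostatic_hypotension",
    "somnolence"              = "drowsiness",
    "vertigo"                 = "dizziness",
    "hypotension"             = "blood_pressure_change",
    "hypertension"            = "blood_pressure_change",
    "blood pressure change"   = "blood_pressure_change",
    "changes in blood pressure" = "blood_pressure_change",
    "bradycardia"             = "blood_pressure_change",
    "ataxia"                  = "impaired_balance",
    "impaired balance"        = "impaired_balance",
    "gait disturbance"        = "impaired_balance",
    "balance disorder"        = "impaired_balance",
    "falls"                   = "fall"
  )
  if (!is.null(extra_synonyms)) {
    if (is.null(names(extra_synonyms)) || any(names(extra_synonyms) == "")) {
      stop("extra_synonyms must be a fully named character vector",
           call. = FALSE)
    }
    bad <- setdiff(extra_synonyms, canonical)
    if (length(bad) > 0) {
      stop(sprintf("extra_synonyms map to non-canonical term(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    synonyms[tolower(names(extra_synonyms))] <- unname(extra_synonyms)
  }
  list(canonical = canonical, synonyms = synonyms)
}

#' Resolve raw SmPC ADE terms to canonical mechanisms
#'
#' @param raw_term Character vector of ADE terms as printed in an SmPC.
#' @param vocabulary A vocabulary from [ade_vocabulary()].
#' @return Character vector of canonical terms. Unresolvable terms raise an
#'   error naming them (class `frids_vocabulary_error`); silent acceptance of
#'   an unmapped term could mis-categorize a drug.
#' @examples
#' resolve_ade_term(c("Somnolence", "bradycardia"))
#' @export
resolve_ade_term <- function(raw_term, vocabulary = ade_vocabulary()) {
  key <- trimws(tolower(raw_term))
  out <- unname(vocabulary$synonyms[key])
  if (anyNA(out)) {
    bad <- unique(raw_term[is.na(out)])
    stop(frids_error(
      sprintf("unresolvable ADE term(s): %s", paste(bad, collapse = ", ")),
      "frids_vocabulary_error"))
  }
  out
}

#' Load vocabulary overrides from a YAML config
#'
#' Reads a YAML file with an optional `synonyms` mapping (raw term ->
#' canonical term) and returns the merged vocabulary.
#'
#' @param path Path to a YAML file.
#' @return A vocabulary list as from [ade_vocabulary()].
#' @export
read_vocabulary_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- NULL
  if (!is.null(cfg$synonyms)) {
    extra <- stats::setNames(as.character(unlist(cfg$synonyms)),
                             names(cfg$synonyms))
  }
  ade_vocabulary(extra_synonyms = extra)
}

# condition constructor shared across modules
frids_error <- function(message, class) {
  structure(class = c(class, "frids_error", "error", "condition"),
            list(message = message, call = NULL))
}
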