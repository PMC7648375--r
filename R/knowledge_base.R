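#' Construct a FRID knowledge base
#'
#' A knowledge base holds one record per active substance (or fixed-dose
#' combination): its ATC code, drug-class label, and the fall-risk ADEs the
#' SmPC lists for it, each tagged with a statutory frequency class.
#' Combination products are single records under their combination ATC code
#' (components are not expanded), because cohort analyses count them as one
#' medicament.
#'
#' @param records Tibble/data frame with columns `ingredient`, `atc_code`,
#'   `drug_class` and optionally `users_n`, `users_pct`,
#'   `annotation_source` (study-usage metadata carried by the packaged
#'   fixture).
#' @param ades Tibble/data frame with columns `ingredient`, `term`
#'   (canonical), `raw_term`, `frequency`; zero rows per ingredient is valid
#'   (drug with no documented fall-risk ADE).
#' @param provenance Free-text source label.
#' @return An object of class `frid_kb`.
#' @seealso [read_knowledge_base()], [frid_knowledge_base()]
#' @export
frid_kb <- function(records, ades = NULL, provenance = "user") {
  records <- tibble::as_tibble(records)
  need <- c("ingredient", "atc_code", "drug_class")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop(frids_error(sprintf("records missing column(s): %s",
                             paste(miss, collapse = ", ")),
                     "frids_format_error"))
  }
  records$ingredient <- normalize_ingredient(records$ingredient)
  records$atc_code <- toupper(trimws(records$atc_code))
  if (!"users_n" %in% names(records)) records$users_n <- NA_integer_
  if (!"users_pct" %in% names(records)) records$users_pct <- NA_real_
  if (!"annotation_source" %in% names(records)) {
    records$annotation_source <- NA_character_
  }
  records$users_n <- suppressWarnings(as.integer(records$users_n))
  records$users_pct <- suppressWarnings(as.double(records$users_pct))
  records$annotation_source <- as.character(records$annotation_source)
  records$annotation_source[!is.na(records$annotation_source) &
                              records$annotation_source == ""] <-
    NA_character_
  records <- records[, c(need, "users_n", "users_pct", "annotation_source")]

  bad_atc <- records$atc_code[!grepl(atc_pattern(), records$atc_code)]
  if (length(bad_atc) > 0) {
    stop(frids_error(sprintf("malformed ATC code(s): %s",
                             paste(unique(bad_atc), collapse = ", ")),
                     "frids_format_error"))
  }
  dup <- records$ingredient[duplicated(records$ingredient)]
  if (length(dup) > 0) {
    stop(frids_error(sprintf("duplicate ingredient(s): %s",
                             paste(unique(dup), collapse = ", ")),
                     "frids_consistency_error"))
  }

  if (is.null(ades)) {
    ades <- tibble::tibble(ingredient = character(), term = character(),
                           raw_term = character(), frequency = character())
  }
  ades <- tibble::as_tibble(ades)
  if (!"raw_term" %in% names(ades)) ades$raw_term <- ades$term
  ades <- ades[, c("ingredient", "term", "raw_term", "frequency")]
  ades$ingredient <- normalize_ingredient(ades$ingredient)
  assert_frequency(ades$frequency)
  vocab <- ade_vocabulary()
  bad_term <- setdiff(unique(ades$term), vocab$canonical)
  if (length(bad_term) > 0) {
    stop(frids_error(sprintf("non-canonical ADE term(s): %s",
                             paste(bad_term, collapse = ", ")),
                     "frids_vocabulary_error"))
  }
  orphan <- setdiff(unique(ades$ingredient), records$ingredient)
  if (length(orphan) > 0) {
    stop(frids_error(sprintf("ADE rows for unknown ingredient(s): %s",
                             paste(orphan, collapse = ", ")),
                     "frids_consistency_error"))
  }

  structure(list(records = records, ades = ades,
                 provenance = as.character(provenance)[1]),
            class = "frid_kb")
}

atc_pattern <- function() "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Normalize an ingredient name
#'
#' Case-folds and trims; combination components are joined by `/`. Salt or
#' ester suffixes are stripped only when listed explicitly in `aliases`
#' (alias -> canonical name); no automatic stemming is attempted, because
#' silent fuzzy matching risks categorizing the wrong substance.
#'
#' @param x Character vector of ingredient names.
#' @param aliases Optional named character vector, alias -> canonical.
#' @return Normalized character vector.
#' @export
normalize_ingredient <- function(x, aliases = NULL) {
  out <- trimws(tolower(x))
  out <- gsub("[[:space:]]*/[[:space:]]*", "/", out)
  if (!is.null(aliases)) {
    key <- match(out, trimws(tolower(names(aliases))))
    hit <- !is.na(key)
    out[hit] <- trimws(tolower(unname(aliases)))[key[hit]]
  }
  out
}

#' @export
print.frid_kb <- function(x, ...) {
  n_ade <- nrow(x$ades)
  cat(sprintf("<frid_kb> %d substances, %d ADE annotations (%s)\n",
              nrow(x$records), n_ade, x$provenance))
  lv <- table(factor(categorize_all(x)$level, levels = risk_levels()))
  cat(sprintf("  risk levels: A=%d B=%d C=%d\n", lv[["A"]], lv[["B"]],
              lv[["C"]]))
  invisible(x)
}

#' @export
length.frid_kb <- function(x) nrow(x$records)

#' Look up knowledge-base records by ingredient name or ATC code
#'
#' Resolution tries an exact ATC code first, then the normalized ingredient
#' name, so ward exports that mix both notations resolve uniformly. ATC
#' lookup can return more than one record where distinct substances share a
#' printed code.
#'
#' @param kb A [frid_kb()].
#' @param key Character vector of ingredient names and/or ATC codes.
#' @param aliases Optional ingredient alias table (see
#'   [normalize_ingredient()]).
#' @return Tibble of matching record rows (one per key occurrence for
#'   ingredient keys). Unknown keys raise a `frids_lookup_error` listing
#'   them; there is no silent drop.
#' @examples
#' kb <- frid_knowledge_base()
#' kb_lookup(kb, c("Metoprolol", "N05AH04"))
#' @export
kb_lookup <- function(kb, key, aliases = NULL) {
  stopifnot(inherits(kb, "frid_kb"))
  is_atc <- grepl(atc_pattern(), toupper(trimws(key)))
  rows <- vector("list", length(key))
  unknown <- character()
  for (i in seq_along(key)) {
    if (is_atc[i]) {
      hit <- kb$records[kb$records$atc_code == toupper(trimws(key[i])), ]
      if (nrow(hit) == 0) {  # ATC-shaped token may still be a weird name
        hit <- kb$records[kb$records$ingredient ==
                            normalize_ingredient(key[i], aliases), ]
      }
    } else {
      hit <- kb$records[kb$records$ingredient ==
                          normalize_ingredient(key[i], aliases), ]
    }
    if (nrow(hit) == 0) unknown <- c(unknown, key[i])
    rows[[i]] <- hit
  }
  if (length(unknown) > 0) {
    stop(frids_error(sprintf("unknown medication(s): %s",
                             paste(unique(unknown), collapse = ", ")),
                     "frids_lookup_error"))
  }
  dplyr::bind_rows(rows)
}

#' ADE annotations for one ingredient
#'
#' @param kb A [frid_kb()].
#' @param ingredient A single normalized ingredient name.
#' @return Tibble of the ingredient's annotations (possibly zero rows).
#' @export
kb_ades <- function(kb, ingredient) {
  kb$ades[kb$ades$ingredient == normalize_ingredient(ingredient), ]
}

#' Read a FRID knowledge base from CSV or JSON
#'
#' The CSV dialect is one row per (ingredient, ADE) pair with columns
#' `ingredient, atc_code, drug_class, ade_term, frequency`; optional columns
#' `raw_term, users_n, users_pct, annotation_source` are carried as metadata.
#' Rows for the same ingredient are merged into one record; an empty
#' `ade_term` denotes a record with no annotation. The JSON dialect is an
#' array of one object per record with an `ades` array and a `meta` object.
#' Raw ADE terms are resolved through the vocabulary; unresolvable terms are
#' an error, not a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param vocabulary Vocabulary from [ade_vocabulary()].
#' @param provenance Source label attached to the result.
#' @return A [frid_kb()].
#' @export
read_knowledge_base <- function(path, format = c("auto", "csv", "json"),
                                vocabulary = ade_vocabulary(),
                                provenance = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop(frids_error(sprintf("no such file: %s", path), "frids_io_error"))
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
    need <- c("ingredient", "atc_code", "drug_class", "ade_term", "frequency")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      stop(frids_error(sprintf("knowledge-base CSV missing column(s): %s",
                               paste(miss, collapse = ", ")),
                       "frids_format_error"))
    }
    raw <- tibble::as_tibble(raw)
    if (nrow(raw) == 0) return(frid_kb(raw[, 1:3], provenance = provenance))
    raw$ingredient <- normalize_ingredient(raw$ingredient)
    bad <- which(!grepl(atc_pattern(), toupper(trimws(raw$atc_code))))
    if (length(bad) > 0) {
      stop(frids_error(
        sprintf("malformed ATC code %s at CSV row %d",
                raw$atc_code[bad[1]], bad[1] + 1L), "frids_format_error"))
    }
    conflicts <- dplyr::summarise(
      dplyr::group_by(raw, .data$ingredient),
      n_atc = dplyr::n_distinct(.data$atc_code), .groups = "drop")
    conflicts <- conflicts$ingredient[conflicts$n_atc > 1]
    if (length(conflicts) > 0) {
      stop(frids_error(
        sprintf("ingredient(s) with conflicting ATC codes: %s",
                paste(conflicts, collapse = ", ")),
        "frids_consistency_error"))
    }
    records <- dplyr::distinct(
      raw[, intersect(names(raw),
                      c("ingredient", "atc_code", "drug_class", "users_n",
                        "users_pct", "annotation_source"))])
    has_ade <- !is.na(raw$ade_term) & trimws(raw$ade_term) != ""
    ades <- raw[has_ade, c("ingredient", "ade_term", "frequency")]
    names(ades)[2] <- "raw_term"
    if ("raw_term" %in% names(raw)) ades$raw_term <- raw$raw_term[has_ade]
    ades$term <- resolve_ade_term(ades$raw_term, vocabulary)
    frid_kb(records, ades, provenance = provenance)
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(objs) == 0) {
      return(frid_kb(tibble::tibble(ingredient = character(),
                                    atc_code = character(),
                                    drug_class = character()),
                     provenance = provenance))
    }
    records <- dplyr::bind_rows(lapply(objs, function(o) {
      meta <- o$meta %||% list()
      tibble::tibble(
        ingredient = o$ingredient, atc_code = o$atc_code,
        drug_class = o$drug_class,
        users_n = as.integer(meta$users_n %||% NA),
        users_pct = as.double(meta$users_pct %||% NA),
        annotation_source = as.character(meta$annotation_source %||% NA))
    }))
    ades <- dplyr::bind_rows(lapply(objs, function(o) {
      if (length(o$ades) == 0) return(NULL)
      dplyr::bind_rows(lapply(o$ades, function(a) {
        tibble::tibble(ingredient = o$ingredient,
                       raw_term = a$raw_term %||% a$term,
                       term_in = a$term, frequency = a$frequency)
      }))
    }))
    if (!is.null(ades) && nrow(ades) > 0) {
      ades$term <- resolve_ade_term(ades$raw_term, vocabulary)
      ades <- ades[, c("ingredient", "term", "raw_term", "frequency")]
    } else {
      ades <- NULL
    }
    frid_kb(records, ades, provenance = provenance)
  }
}

#' Write a FRID knowledge base to CSV or JSON
#'
#' `read_knowledge_base(write_knowledge_base(kb, path))` reproduces `kb`
#' field-for-field in either format.
#'
#' @param kb A [frid_kb()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(kb, "frid_kb"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    rows <- dplyr::left_join(kb$records, kb$ades, by = "ingredient")
    out <- tibble::tibble(
      ingredient = rows$ingredient, atc_code = rows$atc_code,
      drug_class = rows$drug_class,
      ade_term = ifelse(is.na(rows$raw_term), "", rows$raw_term),
      frequency = ifelse(is.na(rows$frequency), "", rows$frequency),
      raw_term = ifelse(is.na(rows$raw_term), "", rows$raw_term),
      users_n = rows$users_n, users_pct = rows$users_pct,
      annotation_source = rows$annotation_source)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    objs <- lapply(seq_len(nrow(kb$records)), function(i) {
      r <- kb$records[i, ]
      a <- kb$ades[kb$ades$ingredient == r$ingredient, ]
      list(
        ingredient = r$ingredient, atc_code = r$atc_code,
        drug_class = r$drug_class,
        ades = lapply(seq_len(nrow(a)), function(j) {
          list(term = a$term[j], raw_term = a$raw_term[j],
               frequency = a$frequency[j])
        }),
        meta = list(users_n = r$users_n, users_pct = r$users_pct,
                    annotation_source = r$annotation_source))
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' The packaged category-A knowledge base
#'
#' Returns the shipped knowledge base of the 102 active substances (including
#' fixed-dose combinations) categorized as high fall risk (category A) in the
#' source study of 188 fall-experienced geriatric patients, with study user
#' counts attached as metadata. The eleven most-used ingredients carry their
#' full published ADE frequency profiles (`annotation_source = "smpc"`); the
#' remaining records carry a minimal placeholder annotation (one
#' common-frequency ADE) sufficient to reproduce category-A membership,
#' flagged `annotation_source = "inferred"` so provenance stays honest.
#'
#' @return A [frid_kb()] with 102 records.
#' @examples
#' kb <- frid_knowledge_base()
#' kb_lookup(kb, "metoprolol")
#' @export
frid_knowledge_base <- function() {
  path <- system.file("extdata", "frid_kb_category_a.csv", package = "frids",
                      mustWork = TRUE)
  read_knowledge_base(path, format = "csv",
                      provenance = "packaged category-A knowledge base")
}

#' Synthetic moderate- and no-risk drug pools
#'
#' The source study reports 29 moderate-risk (B) and 85 no-risk (C)
#' substances but does not name them, so simulation and worked examples need
#' stand-ins. This returns a synthetic pool: 29 category-B substances (one
#' uncommon-frequency ADE each) and 85 category-C substances (one
#' rare-frequency ADE each), under Z-prefixed ATC-pattern codes that cannot
#' collide with real anatomical groups. All names and codes are synthetic.
#'
#' @return A [frid_kb()] with 114 records.
#' @export
synthetic_risk_pool <- function() {
  b <- tibble::tibble(
    ingredient = sprintf("synthetic_moderate_%02d", 1:29),
    atc_code = sprintf("Z01AA%02d", 1:29),
    drug_class = "Synthetic moderate-risk pool (Z01A)",
    annotation_source = "synthetic")
  c_ <- tibble::tibble(
    ingredient = sprintf("synthetic_norisk_%02d", 1:85),
    atc_code = sprintf("Z02AA%02d", 1:85),
    drug_class = "Synthetic no-risk pool (Z02A)",
    annotation_source = "synthetic")
  records <- dplyr::bind_rows(b, c_)
  ades <- tibble::tibble(
    ingredient = records$ingredient,
    term = "dizziness", raw_term = "dizziness",
    frequency = rep(c("uncommon", "rare"), c(29, 85)))
  frid_kb(records, ades, provenance = "synthetic B/C pool")
}

#' Combined reference knowledge base (published A + synthetic B/C)
#'
#' Concatenates [frid_knowledge_base()] with [synthetic_risk_pool()], giving
#' 216 substances whose category partition (102 A / 29 B / 85 C) matches the
#' substance-level structure of the study cohort.
#'
#' @return A [frid_kb()] with 216 records.
#' @export
reference_knowledge_base <- function() {
  a <- frid_knowledge_base()
  s <- synthetic_risk_pool()
  frid_kb(dplyr::bind_rows(a$records, s$records),
          dplyr::bind_rows(a$ades, s$ades),
          provenance = "published category A + synthetic B/C pool")
}
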