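#' Categorize one drug's fall-risk ADE profile
#'
#' Applies the frequency rule to a drug's annotation list: the drug's risk
#' level is the highest risk level attained by any annotation with a known
#' frequency (A if any ADE is very common or common, B if the highest known
#' frequency is uncommon, C otherwise). Annotations with unknown frequency
#' never decide the level — there is no frequency row for them — but their
#' presence is surfaced in `flags` so reviewers see them. A drug with no
#' listed fall-risk ADE is C with an explicit `no_fall_risk_ade_listed` flag,
#' preserving the distinction between "documented as rare" and "nothing
#' documented".
#'
#' @param ades Tibble of annotations with columns `term` and `frequency`
#'   (as in `frid_kb$ades`); zero rows is valid.
#' @param annotation_source Optional source tag from the record metadata;
#'   `"inferred"` adds the `inferred_annotation` flag.
#' @return A list of class `frids_categorization` with `level` (`"A"`,
#'   `"B"` or `"C"`), `deciding_ades` (character vector of terms at the
#'   deciding frequency tier; all ties reported, no first-wins choice) and
#'   `flags` (character subset of `unknown_frequency_present`,
#'   `no_fall_risk_ade_listed`, `inferred_annotation`).
#' @examples
#' kb <- frid_knowledge_base()
#' categorize_drug(kb_ades(kb, "quetiapine"))
#' @export
categorize_drug <- function(ades, annotation_source = NA_character_) {
  ades <- tibble::as_tibble(ades)
  flags <- character()
  if (!is.na(annotation_source) && identical(annotation_source, "inferred")) {
    flags <- c(flags, "inferred_annotation")
  }
  if (nrow(ades) == 0) {
    return(structure(list(level = "C", deciding_ades = character(),
                          flags = c(flags, "no_fall_risk_ade_listed")),
                     class = "frids_categorization"))
  }
  assert_frequency(ades$frequency)
  if (any(ades$frequency == "unknown")) {
    flags <- c(flags, "unknown_frequency_present")
  }
  known <- ades[ades$frequency != "unknown", ]
  if (nrow(known) == 0) {
    # only unknown-frequency annotations: no evidence to elevate
    return(structure(list(level = "C", deciding_ades = character(),
                          flags = flags),
                     class = "frids_categorization"))
  }
  ranks <- frequency_classes()
  known$rank <- ranks$rank[match(known$frequency, ranks$label)]
  top <- min(known$rank)
  deciding <- known[known$rank == top, ]
  structure(list(level = risk_from_frequency(deciding$frequency[1]),
                 deciding_ades = unique(deciding$term),
                 flags = flags),
            class = "frids_categorization")
}

#' @export
print.frids_categorization <- function(x, ...) {
  cat(sprintf("risk level %s; deciding ADEs: %s%s\n", x$level,
              if (length(x$deciding_ades)) {
                paste(x$deciding_ades, collapse = ", ")
              } else "none",
              if (length(x$flags)) {
                paste0(" [", paste(x$flags, collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Categorize every record of a knowledge base
#'
#' @param kb A [frid_kb()].
#' @return Tibble with one row per record: `ingredient`, `atc_code`, `level`,
#'   `deciding_ades` (comma-joined), `flags` (comma-joined). The levels
#'   partition the knowledge base: the A/B/C counts sum to its size.
#' @examples
#' table(categorize_all(frid_knowledge_base())$level)
#' @export
categorize_all <- function(kb) {
  stopifnot(inherits(kb, "frid_kb"))
  if (nrow(kb$records) == 0) {
    return(tibble::tibble(ingredient = character(), atc_code = character(),
                          level = character(), deciding_ades = character(),
                          flags = character()))
  }
  ade_split <- split(kb$ades, factor(kb$ades$ingredient,
                                     levels = kb$records$ingredient))
  res <- lapply(seq_len(nrow(kb$records)), function(i) {
    r <- categorize_drug(ade_split[[kb$records$ingredient[i]]] %||%
                           kb$ades[0, ],
                         kb$records$annotation_source[i])
    tibble::tibble(ingredient = kb$records$ingredient[i],
                   atc_code = kb$records$atc_code[i],
                   level = r$level,
                   deciding_ades = paste(r$deciding_ades, collapse = ","),
                   flags = paste(r$flags, collapse = ","))
  })
  dplyr::bind_rows(res)
}

#' Risk level per ingredient as a named vector
#'
#' Convenience wrapper over [categorize_all()] used by the profiling and
#' summary code.
#'
#' @param kb A [frid_kb()].
#' @return Named character vector ingredient -> level.
#' @export
risk_level_map <- function(kb) {
  res <- categorize_all(kb)
  stats::setNames(res$level, res$ingredient)
}
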