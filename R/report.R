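#' Render a cohort summary as a text report
#'
#' Produces the three familiar table blocks — participant characteristics,
#' admission-score distribution (when supplied) and the top-FRID ranking —
#' with the package's rounding conventions.
#'
#' @param summary A [summarize_cohort()] result.
#' @param distribution Optional [score_distribution()] result.
#' @return Character vector of report lines.
#' @export
render_report_text <- function(summary, distribution = NULL) {
  s <- summary
  lines <- c(
    "== Participants ==",
    sprintf("  %-14s n=%-4d male %d (%d%%)  female %d (%d%%)",
            s$patients$setting, s$patients$n, s$patients$n_male,
            s$patients$pct_male, s$patients$n_female, s$patients$pct_female),
    sprintf("  age mean %.1f (range %d-%d)", s$age$mean, s$age$min,
            s$age$max),
    sprintf("  medicaments per patient mean %.1f (range %d-%d)",
            s$meds_per_patient$mean, s$meds_per_patient$min,
            s$meds_per_patient$max),
    "",
    "== Fall-risk categories ==",
    sprintf("  medicaments (n=%d): %s", s$denominators$medicaments,
            paste(sprintf("%s %d (%d%%)", s$medicaments$level,
                          s$medicaments$n, s$medicaments$pct),
                  collapse = "  ")),
    sprintf("  substances  (n=%d): %s", s$denominators$substances,
            paste(sprintf("%s %d (%d%%)", s$substances$level,
                          s$substances$n, s$substances$pct),
                  collapse = "  ")),
    sprintf("  category A per patient: mean %.1f, min %d, max %d, median %s",
            s$per_patient_a$mean, s$per_patient_a$min, s$per_patient_a$max,
            format(s$per_patient_a$median)))
  if (!is.null(distribution)) {
    lines <- c(lines, "", "== Admission score distribution ==",
               sprintf("  %d  %-12s %3d (%d%%)", distribution$points,
                       distribution$label, distribution$n,
                       distribution$pct),
               sprintf("  score >= 3: %d%%", attr(distribution,
                                                  "share_high")))
  }
  lines <- c(lines, "", "== Top category-A ingredients ==")
  if (nrow(s$top_frids) == 0) {
    lines <- c(lines, "  none")
  } else {
    lines <- c(lines, sprintf("  %-28s %-8s %3d (%.1f%%)",
                              s$top_frids$ingredient, s$top_frids$atc_code,
                              s$top_frids$users_n, s$top_frids$users_pct))
  }
  lines
}

#' Write summary artifacts to a directory
#'
#' CSV outputs are loss-less: unrounded shares accompany the rounded display
#' percentages so downstream users are not bound by the report's rounding
#' conventions.
#'
#' @param summary A [summarize_cohort()] result.
#' @param distribution Optional [score_distribution()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summary, distribution = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    top_frids = file.path(dir, "top_frids.csv"),
    rollup = file.path(dir, "rollup.csv"),
    report = file.path(dir, "report.txt"))
  med <- summary$medicaments
  med$denominator <- "medicaments"
  sub <- summary$substances
  sub$denominator <- "substances"
  utils::write.csv(rbind(med, sub), paths[["summary"]], row.names = FALSE)
  utils::write.csv(summary$top_frids, paths[["top_frids"]],
                   row.names = FALSE)
  roll <- dplyr::bind_rows(lapply(1:3, function(l) {
    r <- summary$rollup[[paste0("level", l)]]
    r$level <- l
    r$share <- r$n / sum(r$n)
    r
  }))
  utils::write.csv(roll, paths[["rollup"]], row.names = FALSE)
  if (!is.null(distribution)) {
    paths <- c(paths, scores = file.path(dir, "score_distribution.csv"))
    d <- as.data.frame(distribution)
    d$share <- d$n / attr(distribution, "n_total")
    utils::write.csv(d, paths[["scores"]], row.names = FALSE)
  }
  writeLines(render_report_text(summary, distribution), paths[["report"]])
  invisible(paths)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `categorize`, `score`, `screen`, `summarize`
#' and `simulate` (see the shipped `inst/cli/frids` wrapper script). Errors
#' print a single machine-parsable line to stderr; exit status 2 flags a
#' usage error, 3 a lookup/validation failure.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status, invisibly.
#' @export
frids_run <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message("usage: frids <categorize|score|screen|summarize|simulate> [options]")
    return(invisible(2L))
  }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  status <- tryCatch({
    switch(cmd,
           categorize = cli_categorize(opts),
           score = cli_score(opts),
           screen = cli_screen(opts),
           summarize = cli_summarize(opts),
           simulate = cli_simulate(opts),
           {
             message(sprintf("error: unknown subcommand '%s'", cmd))
             2L
           })
  },
  frids_lookup_error = function(e) { message("error: ", e$message); 3L },
  frids_error = function(e) { message("error: ", e$message); 3L },
  error = function(e) { message("error: ", e$message); 1L })
  invisible(status %||% 0L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop(frids_error(sprintf("unexpected argument '%s'", args[i]),
                       "frids_usage_error"))
    }
    key <- sub("^--", "", args[i])
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}

cli_kb <- function(opts) {
  if (is.null(opts$kb)) frid_knowledge_base() else
    read_knowledge_base(opts$kb)
}

cli_categorize <- function(opts) {
  kb <- cli_kb(opts)
  res <- categorize_all(kb)
  if (!is.null(opts$drug)) {
    res <- res[res$ingredient == normalize_ingredient(opts$drug), ]
  }
  if (!is.null(opts$out)) {
    utils::write.csv(res, opts$out, row.names = FALSE)
  } else {
    utils::write.csv(res, stdout(), row.names = FALSE)
  }
  0L
}

cli_items <- function(opts) {
  if (is.null(opts$items)) {
    message("usage: frids score --items a,b,... [--meds ...] [--kb KB] [--extended]")
    return(NULL)
  }
  pos <- if (identical(opts$items, "none")) character() else
    strsplit(opts$items, ",", fixed = TRUE)[[1]]
  bad <- setdiff(pos, item_names())
  if (length(bad) > 0) {
    stop(frids_error(sprintf("unknown item(s): %s",
                             paste(bad, collapse = ", ")),
                     "frids_validation_error"))
  }
  stats::setNames(item_names() %in% pos, item_names())
}

cli_score <- function(opts) {
  items <- cli_items(opts)
  if (is.null(items)) return(2L)
  meds <- if (is.null(opts$meds)) character() else
    trimws(strsplit(opts$meds, "[,;]")[[1]])
  sc <- if (isTRUE(opts$extended) || !is.null(opts$meds)) {
    extended_score(items, meds, cli_kb(opts),
                   threshold = as.integer(opts$threshold %||% 1L))
  } else {
    base_score(items)
  }
  cat(sprintf("points %d/%d label %s\n", sc$points, sc$max_points,
              sc$label))
  0L
}

cli_screen <- function(opts) {
  if (is.null(opts$meds)) {
    message("usage: frids screen --meds \"a;b;...\" [--kb KB]")
    return(2L)
  }
  meds <- trimws(strsplit(opts$meds, "[,;]")[[1]])
  prof <- profile_medications(meds, cli_kb(opts))
  cat(sprintf("medications %d: A %d, B %d, C %d\n", prof$n_medications,
              prof$count_A, prof$count_B, prof$count_C))
  if (length(prof$category_a) > 0) {
    cat("category A:", paste(prof$category_a, collapse = ", "), "\n")
  }
  0L
}

cli_summarize <- function(opts) {
  if (is.null(opts$cohort)) {
    message("usage: frids summarize --cohort c.csv [--kb KB] [--top 10] --out dir/")
    return(2L)
  }
  kb <- if (is.null(opts$kb)) reference_knowledge_base() else
    read_knowledge_base(opts$kb)
  cohort <- read_cohort(opts$cohort)
  s <- summarize_cohort(cohort, kb,
                        top_k = as.integer(opts$top %||% 10L),
                        by_setting = isTRUE(opts[["by-setting"]]))
  scores <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    base_score(unlist(cohort[i, item_names()]))
  }))
  dist <- score_distribution(scores)
  out <- opts$out %||% "."
  paths <- render_report(s, dist, out)
  write_manifest(out, inputs = c(cohort = opts$cohort,
                                 kb = opts$kb %||% "<packaged>"),
                 seed = NA)
  message(sprintf("wrote %d files to %s", length(paths) + 1L, out))
  0L
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) {
    message("usage: frids simulate [--n 188] [--seed 1] --out cohort.csv")
    return(2L)
  }
  cfg <- simulation_config(
    n_patients = as.integer(opts$n %||% 188L),
    seed = as.integer(opts$seed %||% 1L))
  write_cohort(generate_cohort(cfg), opts$out)
  0L
}

write_manifest <- function(dir, inputs, seed) {
  manifest <- list(
    package = "frids",
    version = as.character(utils::packageVersion("frids")),
    inputs = as.list(inputs), seed = seed,
    config_hash = sprintf("%08x",
                          sum(utf8ToInt(paste(names(inputs),
                                              unlist(inputs),
                                              collapse = "|")))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(manifest)
}
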