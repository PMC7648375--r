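test_that("CSV rows for one ingredient merge into one annotated record", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ingredient,atc_code,drug_class,ade_term,frequency",
    "quetiapine,N05AH04,Antipsychotics (N05A),dizziness,very_common",
    "quetiapine,N05AH04,Antipsychotics (N05A),drowsiness,very_common",
    "quetiapine,N05AH04,Antipsychotics (N05A),orthostatic hypotension,common"),
    path)
  kb <- read_knowledge_base(path)
  expect_equal(length(kb), 1L)
  ades <- kb_ades(kb, "quetiapine")
  expect_equal(nrow(ades), 3L)
  expect_setequal(ades$term,
                  c("dizziness", "drowsiness", "orthostatic_hypotension"))
})

test_that("degenerate and malformed inputs give named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("ingredient,atc_code,drug_class,ade_term,frequency", path)
  expect_equal(length(read_knowledge_base(path)), 0L)

  writeLines(c("ingredient,atc_code,drug_class,ade_term,frequency",
               "baddrug,XX123,Class,dizziness,common"), path)
  expect_error(read_knowledge_base(path), class = "frids_format_error")
  expect_error(read_knowledge_base(path), "row 2")

  writeLines(c("ingredient,atc_code,drug_class,ade_term,frequency",
               "drug,N05AA01,Class,dizziness,common",
               "drug,N05AA02,Class,drowsiness,common"), path)
  expect_error(read_knowledge_base(path), class = "frids_consistency_error")

  writeLines(c("ingredient,atc_code,drug_class,ade_term,frequency",
               "drug,N05AA01,Class,nausea,common"), path)
  expect_error(read_knowledge_base(path), class = "frids_vocabulary_error")

  expect_error(read_knowledge_base(file.path(tempdir(), "nope.csv")),
               class = "frids_io_error")
})

test_that("read after write is the identity in both formats", {
  for (kb in list(tiny_kb(), frid_knowledge_base())) {
    for (ext in c(".csv", ".json")) {
      path <- withr::local_tempfile(fileext = ext)
      write_knowledge_base(kb, path)
      back <- read_knowledge_base(path, provenance = kb$provenance)
      expect_equal(back$records, kb$records)
      expect_equal(dplyr::arrange(back$ades, ingredient, term, frequency),
                   dplyr::arrange(kb$ades, ingredient, term, frequency))
    }
  }
  # empty knowledge base round-trips to a header-only CSV
  empty <- frid_kb(tibble::tibble(ingredient = character(),
                                  atc_code = character(),
                                  drug_class = character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_knowledge_base(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(length(read_knowledge_base(path)), 0L)
})

test_that("packaged knowledge base carries the published category-A set", {
  kb <- frid_knowledge_base()
  expect_equal(length(kb), 102L)
  expect_false(any(duplicated(kb$records$ingredient)))
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$",
                        kb$records$atc_code)))
  # the eleven most-used ingredients carry full SmPC profiles
  expect_equal(sum(kb$records$annotation_source == "smpc"), 11L)
  expect_equal(sum(kb$records$annotation_source == "inferred"), 91L)

  met <- kb_lookup(kb, "metoprolol")
  expect_equal(met$atc_code, "C07AB02")
  expect_equal(met$users_n, 49L)
  expect_setequal(kb_ades(kb, "metoprolol")$term,
                  c("dizziness", "blood_pressure_change"))

  brz <- kb_ades(kb, "bromazepam")
  expect_true(any(brz$term == "fall" & brz$frequency == "unknown"))

  # JSON round-trip of the packaged fixture keeps all 102 records
  path <- withr::local_tempfile(fileext = ".json")
  write_knowledge_base(kb, path)
  expect_equal(length(read_knowledge_base(path)), 102L)
})

test_that("lookup resolves names and ATC codes to the same records", {
  kb <- frid_knowledge_base()
  expect_equal(kb_lookup(kb, "N05AH04"), kb_lookup(kb, "Quetiapine"))
  expect_error(kb_lookup(kb, c("metoprolol", "unobtanium")),
               class = "frids_lookup_error")
  expect_error(kb_lookup(kb, "unobtanium"), "unobtanium")
})

test_that("ingredient normalization folds case and joins combinations", {
  expect_equal(normalize_ingredient(" Perindopril / Indapamide "),
               "perindopril/indapamide")
  # salt stripping only through an explicit alias table
  expect_equal(normalize_ingredient("metoprolol succinate"),
               "metoprolol succinate")
  expect_equal(normalize_ingredient("metoprolol succinate",
                                    c("metoprolol succinate" = "metoprolol")),
               "metoprolol")
})

test_that("the combined reference base partitions 216 substances as 102/29/85", {
  rkb <- reference_knowledge_base()
  expect_equal(length(rkb), 216L)
  lv <- table(categorize_all(rkb)$level)
  expect_equal(as.integer(lv[c("A", "B", "C")]), c(102L, 29L, 85L))
})
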