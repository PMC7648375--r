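# in-code fixtures shared across the suite

# minimal three-drug knowledge base spanning all risk levels
tiny_kb <- function() {
  frid_kb(
    records = tibble::tibble(
      ingredient = c("alphadrug", "betadrug", "gammadrug"),
      atc_code = c("N05AA01", "C07AB99", "A02BC01"),
      drug_class = c("Antipsychotics (N05A)", "Beta blocking agents (C07A)",
                     "Drug for peptic ulcer and reflux (A02B)")),
    ades = tibble::tibble(
      ingredient = c("alphadrug", "betadrug", "gammadrug"),
      term = c("drowsiness", "dizziness", "dizziness"),
      raw_term = c("somnolence", "dizziness", "dizziness"),
      frequency = c("common", "uncommon", "rare")),
    provenance = "test fixture")
}

# independent oracle: walk the frequency table row by row (most frequent
# first) and return the risk level of the first frequency present
oracle_categorize <- function(freqs) {
  rows <- list(c("very_common", "A"), c("common", "A"), c("uncommon", "B"),
               c("rare", "C"), c("very_rare", "C"))
  for (row in rows) {
    if (row[1] %in% freqs) return(row[2])
  }
  "C"
}

ades_from_freqs <- function(freqs) {
  tibble::tibble(ingredient = "x",
                 term = rep("dizziness", length(freqs)),
                 raw_term = rep("dizziness", length(freqs)),
                 frequency = freqs)
}

# small valid cohort exercising both settings, ATC keys and empty lists
tiny_cohort <- function() {
  as_cohort(tibble::tibble(
    id = c("a", "b", "c"),
    setting = c("hospital", "hospital", "nursing_home"),
    sex = c("female", "male", "female"),
    age = c(80L, 67L, 91L),
    length_of_stay = c("16", "3", "permanent"),
    mmse = c(NA_integer_, 25L, NA_integer_),
    recent_fall = c(TRUE, FALSE, TRUE),
    confusion = c(FALSE, FALSE, TRUE),
    impaired_balance = c(TRUE, FALSE, TRUE),
    dizziness_drowsiness = c(TRUE, FALSE, FALSE),
    medications = list(c("alphadrug", "C07AB99", "alphadrug"),
                       character(),
                       c("gammadrug"))))
}

# published admission-score percentages for the 188-patient cohort
study_score_pcts <- c(3, 9, 35, 37, 16)
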