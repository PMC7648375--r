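test_that("summary denominators and conservation hold on the reference cohort", {
  kb <- reference_knowledge_base()
  coh <- reference_cohort(kb)
  s <- summarize_cohort(coh, kb)
  expect_equal(s$denominators$patients, 188L)
  expect_equal(sum(s$medicaments$n), s$denominators$medicaments)
  expect_equal(sum(s$substances$n), s$denominators$substances)
  for (l in 1:3) {
    roll <- s$rollup[[paste0("level", l)]]
    expect_equal(sum(roll$n), s$medicaments$n[s$medicaments$level == "A"])
  }
  # every (count, pct) pair obeys the stated rounding rule
  expect_equal(s$medicaments$pct,
               round_half_up(100 * s$medicaments$n /
                               s$denominators$medicaments))
  expect_equal(s$substances$pct,
               round_half_up(100 * s$substances$n /
                               s$denominators$substances))
})

test_that("a single-patient cohort gives the trivial summary", {
  kb <- reference_knowledge_base()
  coh <- as_cohort(tibble::tibble(
    id = "solo", setting = "hospital", sex = "female", age = 81L,
    length_of_stay = "5", mmse = 28L, recent_fall = TRUE, confusion = FALSE,
    impaired_balance = FALSE, dizziness_drowsiness = FALSE,
    medications = list(c("metoprolol"))))
  s <- summarize_cohort(coh, kb)
  expect_equal(s$medicaments$pct[s$medicaments$level == "A"], 100)
  expect_equal(s$top_frids$ingredient, "metoprolol")
  expect_equal(s$top_frids$users_n, 1L)
  expect_equal(s$top_frids$users_pct, 100.0)
  expect_error(summarize_cohort(coh[0, ], kb),
               class = "frids_validation_error")
})

test_that("ATC roll-up groups partition the input at every level", {
  meds <- tibble::tibble(
    ingredient = c("a", "b", "c", "d"),
    atc_code = c("N05AH04", "N05BA08", "C07AB02", "C09AA04"))
  l1 <- atc_rollup(meds, 1)
  expect_setequal(l1$group, c("N", "C"))
  expect_equal(sum(l1$n), 4L)
  expect_equal(l1$pct, c(50, 50))
  l2 <- atc_rollup(meds, 2)
  expect_setequal(l2$group, c("N05", "C07", "C09"))
  expect_equal(sum(l2$n), 4L)
  l3 <- atc_rollup(meds, 3)
  expect_equal(sum(l3$n), 4L)
  single <- atc_rollup(meds[1, ], 2)
  expect_equal(single$pct, 100)
  expect_error(atc_rollup(tibble::tibble(ingredient = "x",
                                         atc_code = "bogus"), 1),
               class = "frids_format_error")
})

test_that("top-FRID ranking counts distinct users, not occurrences", {
  kb <- tiny_kb()
  coh <- tiny_cohort()  # patient a lists alphadrug twice
  tf <- top_frids(coh, kb, k = 5)
  expect_equal(tf$ingredient, "alphadrug")
  expect_equal(tf$users_n, 1L)
  expect_equal(tf$users_pct, round_half_up(100 / 3, 1))
  # occurrence count dominates user count for every ingredient
  occ <- frids:::medicament_occurrences(coh, kb)
  occ_n <- table(occ$ingredient)
  expect_true(all(tf$users_n <= occ_n[tf$ingredient]))
  # unused knowledge-base drugs are excluded from the ranking
  expect_false("betadrug" %in% tf$ingredient ||
                 "gammadrug" %in% tf$ingredient)
})

test_that("per-patient category-A statistics match a hand oracle", {
  kb <- tiny_kb()
  # five patients with known A counts 1..5 (alphadrug is the only A drug)
  coh <- as_cohort(tibble::tibble(
    id = paste0("p", 1:5), setting = "hospital", sex = "male",
    age = 70L, length_of_stay = "2", mmse = NA_integer_,
    recent_fall = FALSE, confusion = FALSE, impaired_balance = FALSE,
    dizziness_drowsiness = FALSE,
    medications = lapply(1:5, function(k) rep("alphadrug", k))))
  st <- per_patient_a_stats(coh, kb)
  expect_equal(st$mean, 3.0)
  expect_equal(st$median, 3)
  expect_equal(st$min, 1L)
  expect_equal(st$max, 5L)
  # all-zero cohort
  coh0 <- coh
  coh0$medications <- rep(list(character()), 5)
  expect_equal(unlist(per_patient_a_stats(coh0, kb)),
               c(mean = 0, min = 0, max = 0, median = 0))
})
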