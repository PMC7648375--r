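test_that("base score counts items and maps to the risk labels", {
  all_true <- admission_items(TRUE, TRUE, TRUE, TRUE)
  expect_equal(base_score(all_true)$points, 4L)
  expect_equal(base_score(all_true)$label, "full_risk")
  none <- admission_items(FALSE, FALSE, FALSE, FALSE)
  expect_equal(base_score(none)$points, 0L)
  expect_equal(base_score(none)$label, "no_risk")
  two <- admission_items(TRUE, FALSE, TRUE, FALSE)
  expect_equal(two_score <- base_score(two)$points, 2L)
  expect_equal(base_score(two)$label, "medium_risk")
})

test_that("base score equals the Hamming weight, whatever the item order", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      vals <- sample(c(TRUE, FALSE), 4, replace = TRUE)
      items <- stats::setNames(vals, item_names <- c(
        "recent_fall", "confusion", "impaired_balance",
        "dizziness_drowsiness"))
      shuffled <- items[sample(4)]
      expect_equal(base_score(items)$points, sum(vals))
      expect_equal(base_score(shuffled)$points, sum(vals))
    }
  })
})

test_that("a missing admission item is an error, not a zero", {
  expect_error(admission_items(TRUE, NA, FALSE, TRUE),
               class = "frids_validation_error")
  expect_error(admission_items(TRUE, NA, FALSE, TRUE), "confusion")
  expect_error(base_score(c(recent_fall = TRUE)),
               class = "frids_validation_error")
})

test_that("extended score adds one point for category-A exposure", {
  kb <- reference_knowledge_base()
  items3 <- admission_items(TRUE, TRUE, TRUE, FALSE)
  # one category-A drug among otherwise no-risk medication
  sc <- extended_score(items3, c("metoprolol", "synthetic_norisk_01"), kb)
  expect_equal(sc$points, 4L)
  expect_equal(sc$max_points, 5L)
  expect_true(sc$medication_item)
  # no medication: additive identity
  sc0 <- extended_score(admission_items(FALSE, FALSE, FALSE, FALSE),
                        character(), kb)
  expect_equal(sc0$points, 0L)
  expect_false(sc0$medication_item)
  # ceiling: base 4 plus exposure reaches 5, still full risk
  sc5 <- extended_score(admission_items(TRUE, TRUE, TRUE, TRUE),
                        "quetiapine", kb)
  expect_equal(sc5$points, 5L)
  expect_equal(sc5$label, "full_risk")
  expect_error(extended_score(items3, "unobtanium", kb),
               class = "frids_lookup_error")
  expect_error(extended_score(items3, "metoprolol", kb, threshold = 0),
               class = "frids_validation_error")
})

test_that("extended never scores below base; equality iff below threshold", {
  kb <- reference_knowledge_base()
  med_options <- list(character(), "synthetic_norisk_01",
                      c("metoprolol", "digoxin"),
                      c("synthetic_moderate_01", "quetiapine"))
  withr::with_seed(5, {
    for (rep in 1:30) {
      items <- stats::setNames(sample(c(TRUE, FALSE), 4, replace = TRUE),
                               c("recent_fall", "confusion",
                                 "impaired_balance", "dizziness_drowsiness"))
      meds <- med_options[[sample(length(med_options), 1)]]
      thr <- sample(1:2, 1)
      b <- base_score(items)$points
      e <- extended_score(items, meds, kb, threshold = thr)
      n_a <- profile_medications(meds, kb)$count_A
      expect_gte(e$points, b)
      expect_equal(e$points == b, n_a < thr)
    }
  })
})

test_that("score distribution reproduces the published cohort percentages", {
  points <- rep(0:4, c(5, 17, 66, 69, 31))
  d <- score_distribution(points, max_points = 4)
  expect_equal(d$n, c(5L, 17L, 66L, 69L, 31L))
  expect_equal(d$pct, c(3, 9, 35, 37, 16))
  expect_equal(attr(d, "share_high"), 53)
  expect_equal(attr(d, "n_total"), 188L)
  expect_equal(sum(d$n), 188L)  # conservation
})

test_that("score distribution edge cases and invariants hold", {
  single <- score_distribution(2L, max_points = 4)
  expect_equal(single$n[single$points == 2], 1L)
  expect_equal(single$pct[single$points == 2], 100)

  mixed <- rbind(base_score(admission_items(TRUE, TRUE, TRUE, TRUE)),
                 extended_score(admission_items(TRUE, TRUE, TRUE, TRUE),
                                character(), reference_knowledge_base()))
  expect_error(score_distribution(mixed), class = "frids_validation_error")
  expect_error(score_distribution(integer(0), max_points = 4),
               class = "frids_validation_error")

  # integer percentages sum to 100 give or take rounding slack
  withr::with_seed(9, {
    for (rep in 1:20) {
      pts <- sample(0:4, sample(5:200, 1), replace = TRUE)
      d <- score_distribution(pts, max_points = 4)
      expect_lte(abs(sum(d$pct) - 100), 2)
    }
  })
})

test_that("percentage rounding rounds half away from zero", {
  expect_equal(round_half_up(100 * 69 / 188), 37)
  expect_equal(round_half_up(100 * 31 / 188), 16)
  expect_equal(round_half_up(100 * 88 / 188), 47)
  expect_equal(round_half_up(100 * 49 / 188, 1), 26.1)
  expect_equal(round_half_up(100 * 36 / 188, 1), 19.1)
  expect_equal(round_half_up(100 * 24 / 188, 1), 12.8)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)  # base round() would give 2
})
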