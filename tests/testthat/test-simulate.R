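test_that("generation is deterministic under a fixed seed, through write", {
  cfg <- simulation_config(n_patients = 50, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa)
  write_cohort(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  # a different seed gives a different cohort
  expect_false(identical(
    a, generate_cohort(simulation_config(n_patients = 50, seed = 8))))
  # the caller's RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(before, .Random.seed)
})

test_that("every generated patient passes cohort validation", {
  coh <- generate_cohort(simulation_config(n_patients = 188, seed = 7))
  expect_equal(nrow(coh), 188L)
  expect_s3_class(coh, "frids_cohort")  # as_cohort already validated
  expect_true(all(coh$age >= 60 & coh$age <= 97))
  expect_true(all(lengths(coh$medications) >= 2 &
                    lengths(coh$medications) <= 17))
  expect_true(all(coh$length_of_stay[coh$setting == "nursing_home"] ==
                    "permanent"))
  expect_true(all(is.na(coh$mmse[coh$setting == "nursing_home"])))
  expect_true(all(coh$mmse[coh$setting == "hospital"] >= 5 &
                    coh$mmse[coh$setting == "hospital"] <= 30))
  # medication lists resolve and are duplicate-free within a patient
  kb <- reference_knowledge_base()
  expect_silent(profile_cohort(coh, kb))
  expect_true(all(!vapply(coh$medications, anyDuplicated, 0L) > 0))
})

test_that("large-sample marginals recover the configured parameters", {
  cfg <- simulation_config(n_patients = 2000, seed = 13)
  coh <- generate_cohort(cfg)
  n <- nrow(coh)
  se <- function(x) stats::sd(x) / sqrt(n)

  meds <- lengths(coh$medications)
  expect_lt(abs(mean(meds) - cfg$meds_per_patient$mean), 3 * se(meds))
  expect_lt(abs(mean(coh$age) - cfg$age$mean), 3 * se(coh$age))

  p_hosp <- mean(coh$setting == "hospital")
  expect_lt(abs(p_hosp - cfg$setting_split),
            3 * sqrt(cfg$setting_split * (1 - cfg$setting_split) / n))
  hosp <- coh[coh$setting == "hospital", ]
  p_male <- mean(hosp$sex == "male")
  p0 <- cfg$sex_split[["hospital"]]
  expect_lt(abs(p_male - p0), 3 * sqrt(p0 * (1 - p0) / nrow(hosp)))

  # essentially everyone is exposed to at least one category-A drug
  prof <- profile_cohort(coh, reference_knowledge_base())
  expect_gt(mean(prof$count_A >= 1), 0.9)
})

test_that("item-prevalence calibration fits the published distribution closely", {
  cal <- calibrate_item_prevalences(study_score_counts())
  expect_length(cal$probabilities, 4L)
  expect_true(all(cal$probabilities >= 0 & cal$probabilities <= 1))
  expect_lt(cal$distance, 0.1)
  # the fitted pmf is the exact Poisson-binomial of the returned parameters
  expect_equal(sum(cal$fitted), 1, tolerance = 1e-12)

  # degenerate targets sit on the cube's corners with zero distance
  lo <- calibrate_item_prevalences(c(10, 0, 0, 0, 0))
  expect_equal(lo$probabilities, rep(0, 4))
  expect_equal(lo$distance, 0)
  hi <- calibrate_item_prevalences(c(0, 0, 0, 0, 10))
  expect_equal(hi$probabilities, rep(1, 4))
  expect_equal(hi$distance, 0)
  expect_error(calibrate_item_prevalences(c(1, 2, 3)),
               class = "frids_config_error")
})

test_that("simulated admission scores approximate the published distribution", {
  coh <- generate_cohort(simulation_config(n_patients = 2000, seed = 19))
  pts <- coh$recent_fall + coh$confusion + coh$impaired_balance +
    coh$dizziness_drowsiness
  d <- score_distribution(pts, max_points = 4)
  target <- study_score_counts() / sum(study_score_counts())
  tv <- 0.5 * sum(abs(d$n / sum(d$n) - target))
  # calibration residual (~0.04) plus Monte-Carlo noise
  expect_lt(tv, 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(setting_split = 1.4),
               class = "frids_config_error")
  expect_error(simulation_config(age = list(mean = 50, min = 60, max = 97,
                                            sd = 8)),
               class = "frids_config_error")
  expect_error(simulation_config(n_patients = 0),
               class = "frids_config_error")
  expect_error(generate_cohort(simulation_config(drug_pool = tiny_kb(),
                                                 seed = 1)),
               class = "frids_config_error")
})
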