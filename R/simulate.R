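#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the study cohort's published marginals: 188 patients of
#' whom 128 hospital inpatients and 60 nursing-home residents; sex split per
#' setting (67/128 male in hospital, 18/60 in the nursing home); age mean 79
#' on 60-97 (truncated discretized normal); 9.3 medicaments per patient on
#' 2-17 (truncated negative binomial — counts of concurrent medicines are
#' over-dispersed); hospital MMSE mean 21.7 on 5-30; hospital length of stay
#' mean 15.8 days on 1-56; admission-item prevalences calibrated so the
#' implied score distribution approximates the published one. The drug pool
#' defaults to [reference_knowledge_base()], with category sampling weights
#' proportional to the published medicament-level category shares
#' (710/331/707 of 1748) and within-category-A weights proportional to
#' published user counts; the B/C pools are synthetic and weighted
#' uniformly, because no moderate/no-risk substances are published.
#'
#' The standard deviations are not all published (the printed age SD of 18.5
#' is inconsistent with the 60-97 range); defaults use realistic values for
#' a geriatric inpatient cohort (age SD 8, MMSE SD 6) and a dispersion for
#' the count distributions matched to the published ranges
#' (SD approximately range/4).
#'
#' @param n_patients Cohort size.
#' @param setting_split Proportion of hospital patients.
#' @param sex_split Named vector: probability of `male` per setting.
#' @param age,meds_per_patient,mmse,length_of_stay Lists with `mean`, `min`,
#'   `max` (and `sd` where normal) for the truncated sampling distributions.
#' @param drug_pool A [frid_kb()] to sample medications from.
#' @param category_weights Sampling weight of risk categories A/B/C.
#' @param item_prevalences Per-item probabilities for the four admission
#'   items, or `NULL` to calibrate them from `score_target`.
#' @param score_target Score-count target for calibration (see
#'   [calibrate_item_prevalences()]).
#' @param seed Integer RNG seed.
#' @return A list of class `frids_sim_config`.
#' @export
simulation_config <- function(n_patients = 188,
                              setting_split = 128 / 188,
                              sex_split = c(hospital = 67 / 128,
                                            nursing_home = 18 / 60),
                              age = list(mean = 79, min = 60, max = 97,
                                         sd = 8),
                              meds_per_patient = list(mean = 9.3, min = 2,
                                                      max = 17),
                              mmse = list(mean = 21.7, min = 5, max = 30,
                                          sd = 6),
                              length_of_stay = list(mean = 15.8, min = 1,
                                                    max = 56),
                              drug_pool = NULL,
                              category_weights = c(A = 710, B = 331,
                                                   C = 707) / 1748,
                              item_prevalences = NULL,
                              score_target = study_score_counts(),
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              setting_split = setting_split, sex_split = sex_split,
              age = age, meds_per_patient = meds_per_patient, mmse = mmse,
              length_of_stay = length_of_stay, drug_pool = drug_pool,
              category_weights = category_weights,
              item_prevalences = item_prevalences,
              score_target = score_target, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "frids_sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$setting_split, cfg$sex_split, cfg$item_prevalences)
  if (any(props < 0 | props > 1)) {
    stop(frids_error("proportions must lie in [0, 1]",
                     "frids_config_error"))
  }
  for (nm in c("age", "meds_per_patient", "mmse", "length_of_stay")) {
    d <- cfg[[nm]]
    if (!(d$min <= d$mean && d$mean <= d$max)) {
      stop(frids_error(sprintf("%s: need min <= mean <= max", nm),
                       "frids_config_error"))
    }
  }
  if (cfg$n_patients < 1) {
    stop(frids_error("n_patients must be >= 1", "frids_config_error"))
  }
  invisible(cfg)
}

# pmf of a discretized normal truncated to min..max, with the location
# parameter solved so the truncated mean equals the configured mean
truncated_normal_pmf <- function(mean, min, max, sd) {
  k <- min:max
  mu <- stats::uniroot(function(m) {
    w <- stats::dnorm(k, m, sd)
    sum(k * w) / sum(w) - mean
  }, interval = c(min - 10 * sd, max + 10 * sd))$root
  w <- stats::dnorm(k, mu, sd)
  w / sum(w)
}

# pmf of a negative binomial truncated to min..max; the size parameter comes
# from moment matching (variance ~ (range/4)^2) and the untruncated mean is
# solved so the truncated mean equals the configured mean
truncated_nbinom_pmf <- function(mean, min, max) {
  k <- min:max
  sigma2 <- max(((max - min) / 4)^2, mean + 0.5)
  size <- mean^2 / (sigma2 - mean)
  mu <- stats::uniroot(function(m) {
    w <- stats::dnbinom(k, size = size, mu = m)
    sum(k * w) / sum(w) - mean
  }, interval = c(1e-6, 10 * max))$root
  w <- stats::dnbinom(k, size = size, mu = mu)
  w / sum(w)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort from a [simulation_config()]. Every generated patient
#' passes cohort validation, and output is byte-for-byte reproducible for a
#' given seed (the caller's RNG state is untouched). Medication lists are
#' sampled per patient without replacement from the weighted pool; list
#' lengths come from the truncated count distribution, clipped to the pool
#' size.
#'
#' @param config A [simulation_config()].
#' @return A cohort tibble of `n_patients` rows.
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 20, seed = 7))
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  kb <- config$drug_pool %||% reference_knowledge_base()
  pool_w <- pool_weights(kb, config$category_weights)
  if (nrow(kb$records) < config$meds_per_patient$max) {
    stop(frids_error("drug pool smaller than the maximum medications per patient",
                     "frids_config_error"))
  }
  p_items <- config$item_prevalences %||%
    calibrate_item_prevalences(config$score_target)$probabilities

  withr::with_seed(config$seed, {
    n <- config$n_patients
    setting <- ifelse(stats::runif(n) < config$setting_split,
                      "hospital", "nursing_home")
    sex <- ifelse(stats::runif(n) < config$sex_split[setting],
                  "male", "female")
    age <- sample_trunc(n, config$age, truncated_normal_pmf,
                        sd = config$age$sd)
    m_cfg <- config$meds_per_patient
    m_pmf <- truncated_nbinom_pmf(m_cfg$mean, m_cfg$min, m_cfg$max)
    n_meds <- pmin(sample(m_cfg$min:m_cfg$max, n, replace = TRUE,
                          prob = m_pmf), nrow(kb$records))
    meds <- lapply(n_meds, function(m) {
      sample(kb$records$ingredient, m, replace = FALSE, prob = pool_w)
    })
    items <- matrix(stats::runif(4 * n) < rep(p_items, each = n), nrow = n)
    mmse <- ifelse(setting == "hospital",
                   sample_trunc(n, config$mmse, truncated_normal_pmf,
                                sd = config$mmse$sd), NA_integer_)
    los_cfg <- config$length_of_stay
    los <- ifelse(setting == "hospital",
                  as.character(sample_trunc(n, los_cfg,
                                            truncated_nbinom_pmf)),
                  "permanent")
    as_cohort(tibble::tibble(
      id = sprintf("sim%05d", seq_len(n)),
      setting = setting, sex = sex, age = age,
      length_of_stay = los, mmse = as.integer(mmse),
      recent_fall = items[, 1], confusion = items[, 2],
      impaired_balance = items[, 3], dizziness_drowsiness = items[, 4],
      medications = meds))
  })
}

sample_trunc <- function(n, cfg, pmf_fun, ...) {
  pmf <- pmf_fun(cfg$mean, cfg$min, cfg$max, ...)
  sample(cfg$min:cfg$max, n, replace = TRUE, prob = pmf)
}

# per-record sampling weights: category share times within-category weight
# (published user counts within A, uniform within B/C)
pool_weights <- function(kb, category_weights) {
  level <- unname(risk_level_map(kb)[kb$records$ingredient])
  w <- numeric(nrow(kb$records))
  for (lv in risk_levels()) {
    sel <- level == lv
    if (!any(sel)) next
    within <- if (lv == "A" && any(!is.na(kb$records$users_n[sel]))) {
      u <- replace(kb$records$users_n[sel],
                   is.na(kb$records$users_n[sel]), 1L)
      u / sum(u)
    } else {
      rep(1 / sum(sel), sum(sel))
    }
    w[sel] <- category_weights[[lv]] * within
  }
  w / sum(w)
}

#' Calibrate admission-item prevalences to a score distribution
#'
#' The published data give only the marginal distribution of the 4-item
#' admission score, not the item-level joint distribution, so the simulator
#' assumes independent Bernoulli items — the minimal assumption — and
#' chooses the four item probabilities whose implied score distribution (a
#' Poisson-binomial over 4 items) minimizes the total variation distance to
#' the target. Independence cannot fit every target exactly; the achieved
#' distance is reported rather than hidden.
#'
#' @param target Named vector of patient counts for scores `"0"`..`"4"`
#'   (or an unnamed length-5 vector in score order).
#' @return A list: `probabilities` (length 4), `fitted` (implied score
#'   distribution), `target_distribution`, `distance` (total variation).
#' @examples
#' calibrate_item_prevalences(study_score_counts())$distance
#' @export
calibrate_item_prevalences <- function(target = study_score_counts()) {
  if (length(target) != 5 || any(target < 0) || sum(target) == 0) {
    stop(frids_error("target must be 5 nonnegative counts for scores 0..4",
                     "frids_config_error"))
  }
  tgt <- as.numeric(target) / sum(target)
  tv <- function(p) 0.5 * sum(abs(poisson_binomial_pmf(p) - tgt))
  # degenerate targets sit on the boundary of the probability cube
  if (tgt[1] == 1) p <- rep(0, 4)
  else if (tgt[5] == 1) p <- rep(1, 4)
  else {
    start <- rep(sum(0:4 * tgt) / 4, 4)
    fit <- stats::optim(start, tv, method = "L-BFGS-B",
                        lower = 1e-9, upper = 1 - 1e-9)
    p <- fit$par
  }
  list(probabilities = p, fitted = poisson_binomial_pmf(p),
       target_distribution = tgt, distance = tv(p))
}

# exact Poisson-binomial pmf over 0..4 via the probability generating
# polynomial
poisson_binomial_pmf <- function(p) {
  coef <- 1
  for (pi in p) coef <- c(coef * (1 - pi), 0) + c(0, coef * pi)
  coef
}
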