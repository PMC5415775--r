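#' Configuration for the synthetic clinical cohort
#'
#' Describes a cohort of nondiffuse-glioma patients whose FGFR1/FGFR3
#' immunostaining scores (0-3) are associated, through a logistic model,
#' with tumour grade, location and pediatric age, and whose survival
#' follows an exponential proportional-hazards model in the staining group.
#' Defaults mirror the structure of a real ependymoma cohort of 108
#' samples: grade marginals 18/68/22 (I/II/III), locations roughly
#' 40/25/35% spinal/cerebellar/cerebral, ages centred at 35 +/- 21 years,
#' a hazard ratio of 1.82 for high staining, and a baseline hazard chosen
#' so that 5-year survival is about 82% (0.0033 events/month).
#'
#' The staining-high probability follows
#' `logit(p) = alpha + log(or_grade) * (grade - II) + log(or_cerebral) * cerebral
#'  + log(or_pediatric) * pediatric`, separately per marker.
#'
#' @param n_patients Cohort size.
#' @param grade_probs Probabilities for grades I, II, III (sum to 1).
#' @param location_probs Probabilities for spinal, cerebellar, cerebral.
#' @param age_mean,age_sd,age_min,age_max Age distribution (normal,
#'   truncated to \[age_min, age_max\]).
#' @param pediatric_cutoff Age (years) below which a patient is pediatric.
#' @param baseline_logit Intercept of the staining-high logistic model.
#' @param or_grade Odds ratio per grade step (I -> II -> III) for high staining.
#' @param or_cerebral Odds ratio of cerebral vs other locations.
#' @param or_pediatric Odds ratio of pediatric vs adult.
#' @param p_score_high Probabilities of scores (2, 3) given high staining.
#' @param p_score_low Probabilities of scores (0, 1) given low staining.
#' @param baseline_hazard Events per month for the staining-low group.
#' @param hazard_ratio Hazard ratio of FGFR3-high vs -low (death).
#' @param recurrence_hazard,recurrence_hr Same for recurrence.
#' @param censor_horizon Administrative censoring time (months).
#' @param prolif_cuts Tertile boundaries (on the standard-normal
#'   proliferation index) separating proliferation groups 1/2/3.
#' @param missing_score_rate Fraction of IHC scores set missing at random.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 108L,
                          grade_probs = c(I = 18, II = 68, III = 22) / 108,
                          location_probs = c(spinal = 0.40, cerebellar = 0.25, cerebral = 0.35),
                          age_mean = 35, age_sd = 21, age_min = 1, age_max = 75,
                          pediatric_cutoff = 16,
                          baseline_logit = -2.0,
                          or_grade = 3, or_cerebral = 4, or_pediatric = 2,
                          p_score_high = c(0.7, 0.3),
                          p_score_low = c(0.75, 0.25),
                          baseline_hazard = 0.0033,
                          hazard_ratio = 1.82,
                          recurrence_hazard = 0.006,
                          recurrence_hr = 2.0,
                          censor_horizon = 300,
                          prolif_cuts = c(-0.43, 0.43),
                          missing_score_rate = 0.03) {
  stopifnot(n_patients >= 1,
            abs(sum(grade_probs) - 1) < 1e-8,
            abs(sum(location_probs) - 1) < 1e-8,
            or_grade > 0, or_cerebral > 0, or_pediatric > 0,
            hazard_ratio > 0, recurrence_hr > 0,
            baseline_hazard > 0, recurrence_hazard > 0,
            censor_horizon > 0, pediatric_cutoff > 0,
            abs(sum(p_score_high) - 1) < 1e-8,
            abs(sum(p_score_low) - 1) < 1e-8,
            missing_score_rate >= 0, missing_score_rate < 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a clinical cohort
#'
#' Draws per-patient demographics, IHC scores whose high/low status follows
#' the configured logistic model, a proliferation group (tertiles of a
#' normal index, shifted upward for staining-high cases), and survival
#' and recurrence times from exponential proportional-hazards models with
#' administrative censoring at the configured horizon.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return data.table of class `cohort_table`: `patient_id`, `age`,
#'   `pediatric`, `sex`, `grade`, `location`, `fgfr1_score`, `fgfr3_score`,
#'   `prolif_group`, `followup_months`, `death`, `recurrence_months`,
#'   `recurrence`, `primary_tumor`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_patients

  grade <- factor(sample(c("I", "II", "III"), n, TRUE, config$grade_probs),
                  levels = c("I", "II", "III"))
  location <- factor(sample(c("spinal", "cerebellar", "cerebral"), n, TRUE,
                            config$location_probs),
                     levels = c("spinal", "cerebellar", "cerebral"))
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_min), config$age_max)
  pediatric <- age < config$pediatric_cutoff
  sex <- sample(c("M", "F"), n, TRUE)

  lp <- config$baseline_logit +
    log(config$or_grade) * (as.integer(grade) - 2L) +
    log(config$or_cerebral) * (location == "cerebral") +
    log(config$or_pediatric) * pediatric
  p_high <- stats::plogis(lp)

  draw_score <- function(high) {
    s <- integer(length(high))
    s[high]  <- sample(c(2L, 3L), sum(high),  TRUE, config$p_score_high)
    s[!high] <- sample(c(0L, 1L), sum(!high), TRUE, config$p_score_low)
    s
  }
  fgfr3_high <- stats::runif(n) < p_high
  fgfr1_high <- stats::runif(n) < p_high   # same model, independent draw
  fgfr3_score <- draw_score(fgfr3_high)
  fgfr1_score <- draw_score(fgfr1_high)
  if (config$missing_score_rate > 0) {
    fgfr3_score[stats::runif(n) < config$missing_score_rate] <- NA_integer_
    fgfr1_score[stats::runif(n) < config$missing_score_rate] <- NA_integer_
  }

  # proliferation: log-normal index, staining-high cases shifted up
  prolif_index <- stats::rnorm(n, mean = 0.5 * fgfr3_high, sd = 1)
  prolif_group <- cut(prolif_index, c(-Inf, config$prolif_cuts, Inf),
                      labels = FALSE)

  h_death <- config$baseline_hazard * config$hazard_ratio^fgfr3_high
  t_death <- stats::rexp(n, h_death)
  death <- t_death <= config$censor_horizon
  followup <- pmin(t_death, config$censor_horizon)

  h_rec <- config$recurrence_hazard * config$recurrence_hr^fgfr3_high
  t_rec <- stats::rexp(n, h_rec)
  recurrence <- t_rec <= pmin(t_death, config$censor_horizon)
  rec_months <- pmin(t_rec, followup)

  out <- data.table::data.table(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(age, 1), pediatric = pediatric, sex = sex,
    grade = as.character(grade), location = as.character(location),
    fgfr1_score = fgfr1_score, fgfr3_score = fgfr3_score,
    prolif_group = as.integer(prolif_group),
    followup_months = round(followup, 2), death = death,
    recurrence_months = round(rec_months, 2), recurrence = recurrence,
    primary_tumor = TRUE)
  data.table::setattr(out, "class", c("cohort_table", class(out)))
  out[]
}

#' Write / read a cohort table as TSV
#'
#' Missing values are written as empty fields. The header is the column set
#' documented in [simulate_cohort()].
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- data.table::fread(path, sep = "\t", na.strings = "",
                           colClasses = list(character = c("patient_id", "sex",
                                                           "grade", "location")))
  data.table::setattr(out, "class", c("cohort_table", class(out)))
  out[]
}
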