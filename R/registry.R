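#' Simulate a patient registry for the nested case-control pipeline
#'
#' Generates a registry emulating an abdominal-ultrasonography cohort: age,
#' sex, BMI, atrial fibrillation (AF), heart-failure NYHA class, digoxin
#' exposure and fatty-liver outcome. Digoxin is prescribed preferentially to
#' AF and older patients (the confounding that motivates matching); fatty
#' liver follows a logistic model with the stated conditional odds ratio for
#' digoxin given the confounders. Ages are drawn wider than the 20-80
#' inclusion window and a fraction of subjects carry NYHA class II-IV or a
#' missing field, so cohort filtering has real work to do.
#'
#' @param n number of subjects (>= 1).
#' @param digoxin_rate target baseline digoxin exposure rate.
#' @param fl_rate_unexposed fatty-liver probability for an unexposed subject
#'   at the covariate reference (age 62, BMI 22.5, female, no AF).
#' @param fl_odds_ratio_digoxin conditional odds ratio of fatty liver for
#'   digoxin exposure (protective < 1).
#' @param missing_rate probability a subject has one required field missing.
#' @param hf_rate probability of heart failure NYHA class II-IV.
#' @param seed integer seed.
#' @param age_mean,age_sd,age_range age distribution (normal, truncated to
#'   `age_range`); the default range 18-92 extends beyond the 20-80 window.
#' @param bmi_mean,bmi_sd BMI distribution.
#' @param male_rate probability of male sex.
#' @param confounding scale on the confounder coefficients (0 switches all
#'   confounding off, making the crude 2x2 odds ratio estimate the
#'   conditional one).
#' @return a `registry` data.frame with columns `subject_id,age,sex,bmi,af,
#'   hf_nyha,digoxin,fatty_liver,exam_date`.
#' @export
simulate_registry <- function(n, digoxin_rate = 0.018,
                              fl_rate_unexposed = 0.238,
                              fl_odds_ratio_digoxin = 0.58,
                              missing_rate = 0.02, hf_rate = 0.012, seed,
                              age_mean = 62, age_sd = 12,
                              age_range = c(18, 92),
                              bmi_mean = 22.5, bmi_sd = 3.2,
                              male_rate = 0.55, confounding = 1) {
  if (n < 1) stop_input("n must be >= 1")
  rates <- c(digoxin_rate, fl_rate_unexposed, missing_rate, hf_rate,
             male_rate)
  if (any(rates < 0 | rates > 1)) stop_input("rates must be in [0, 1]")
  if (fl_odds_ratio_digoxin <= 0) stop_input("odds ratio must be > 0")
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, age_mean, age_sd), age_range[1]), age_range[2])
    male <- runif(n) < male_rate
    bmi <- pmax(rnorm(n, bmi_mean, bmi_sd), 12)
    af <- runif(n) < plogis(qlogis(0.09) + confounding * 0.05 * (age - age_mean))
    # digoxin indication: AF and age
    p_dig <- plogis(qlogis(digoxin_rate) +
                      confounding * (2.5 * af + 0.03 * (age - age_mean)))
    digoxin <- runif(n) < p_dig
    lp <- qlogis(fl_rate_unexposed) + log(fl_odds_ratio_digoxin) * digoxin +
      confounding * (0.03 * (age - age_mean) + 0.08 * (bmi - bmi_mean) +
                       0.3 * male + 0.5 * af)
    fatty_liver <- runif(n) < plogis(lp)
    hf <- runif(n) < hf_rate
    hf_nyha <- ifelse(hf, sample(2:4, n, replace = TRUE),
                      ifelse(runif(n) < 0.05, 1L, NA_integer_))
    sex <- ifelse(male, "M", "F")
    # missingness: blank one required field
    miss <- which(runif(n) < missing_rate)
    which_field <- sample(c("bmi", "age", "sex"), length(miss),
                          replace = TRUE)
    bmi[miss[which_field == "bmi"]] <- NA_real_
    age[miss[which_field == "age"]] <- NA_real_
    sex[miss[which_field == "sex"]] <- NA_character_
    exam_date <- as.Date("2011-01-01") +
      sample.int(3650, n, replace = TRUE) - 1L
    out <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)), age = age, sex = sex,
      bmi = bmi, af = af, hf_nyha = hf_nyha, digoxin = digoxin,
      fatty_liver = fatty_liver, exam_date = exam_date,
      stringsAsFactors = FALSE)
    class(out) <- c("registry", "data.frame")
    out
  })
}

#' Write / read a registry CSV
#' @param registry a `registry` data.frame.
#' @param path file path.
#' @export
write_registry_csv <- function(registry, path) {
  write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  if (!file.exists(path)) stop_input("registry CSV not found: ", path)
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (nm in c("af", "digoxin", "fatty_liver")) {
    if (nm %in% names(out)) out[[nm]] <- as.logical(out[[nm]])
  }
  if ("exam_date" %in% names(out)) out$exam_date <- as.Date(out$exam_date)
  class(out) <- c("registry", "data.frame")
  out
}
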