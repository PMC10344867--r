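test_that("cohort filters match the hand-filtered toy registry", {
  reg <- toy_registry() # 2x NYHA III, 1x age 85, 1x missing BMI
  f <- apply_cohort_filters(reg)
  expect_identical(f$report$n_input, 10L)
  expect_identical(f$report$n_excluded_total, 4L)
  expect_identical(f$report$n_remaining, 6L)
  expect_identical(unname(f$report$n_excluded_by_reason),
                   c(1L, 2L, 1L)) # missing, heart failure, age
  # conservation
  expect_identical(f$report$n_input - f$report$n_excluded_total,
                   f$report$n_remaining)
  expect_identical(sum(f$report$n_excluded_by_reason),
                   f$report$n_excluded_total)
  # empty registry
  f0 <- apply_cohort_filters(reg[0, ])
  expect_identical(f0$report$n_input, 0L)
  expect_identical(f0$report$n_remaining, 0L)
  # malformed types error
  bad <- reg
  bad$digoxin <- as.integer(bad$digoxin)
  expect_error(apply_cohort_filters(bad), "digoxin",
               class = "liposcreen_input_error")
})

test_that("duplicate subjects keep the most recent ultrasound record", {
  reg <- toy_registry()
  reg$exam_date <- as.Date("2015-01-01")
  dup <- reg[1, ]
  dup$exam_date <- as.Date("2019-06-01")
  dup$fatty_liver <- FALSE # later record differs
  both <- rbind(reg, dup)
  f <- apply_cohort_filters(both)
  expect_identical(f$report$n_input, 10L)
  kept <- f$registry[f$registry$subject_id == "T01", ]
  expect_false(kept$fatty_liver)
})

test_that("1:1 matching is exact on strata, caliper-bounded and greedy", {
  mk <- function(id, age, sex, bmi, af, digoxin) {
    data.frame(subject_id = id, age = age, sex = sex, bmi = bmi, af = af,
               hf_nyha = NA_integer_, digoxin = digoxin,
               fatty_liver = FALSE, stringsAsFactors = FALSE)
  }
  # identical control -> distance 0
  reg <- rbind(mk("case1", 70, "M", 21, TRUE, TRUE),
               mk("ctl1", 70, "M", 21, TRUE, FALSE))
  m <- match_case_control(reg)
  expect_identical(nrow(m$pairs), 1L)
  expect_identical(m$pairs$distance, 0)
  # nearest of two eligible controls wins (exhaustive distance comparison)
  reg2 <- rbind(mk("case1", 70, "M", 21, TRUE, TRUE),
                mk("ctlA", 70, "M", 21, TRUE, FALSE),
                mk("ctlB", 71, "M", 21, TRUE, FALSE))
  m2 <- match_case_control(reg2)
  expect_identical(m2$pairs$control_id, "ctlA")
  # caliper violation -> unmatched and reported
  reg3 <- rbind(mk("case1", 70, "M", 21, TRUE, TRUE),
                mk("ctlC", 75, "M", 21, TRUE, FALSE),
                mk("ctlD", 70, "M", 26, TRUE, FALSE))
  m3 <- match_case_control(reg3)
  expect_identical(nrow(m3$pairs), 0L)
  expect_identical(m3$unmatched_cases, "case1")
  # exact variables never cross strata
  reg4 <- rbind(mk("case1", 70, "M", 21, TRUE, TRUE),
                mk("ctlE", 70, "F", 21, TRUE, FALSE))
  expect_warning(m4 <- match_case_control(reg4), "stratum")
  expect_identical(nrow(m4$pairs), 0L)
  # both pools must be non-empty
  expect_error(match_case_control(mk("c", 70, "M", 21, TRUE, TRUE)),
               class = "liposcreen_input_error")
})

test_that("matched cohorts are balanced and within calipers (property)", {
  reg <- simulate_registry(20000, seed = 9)
  f <- apply_cohort_filters(reg)
  m <- match_case_control(f$registry, matching_criteria())
  co <- m$cohort
  cases <- co[co$matched_group == "case", ]
  ctrls <- co[co$matched_group == "control", ]
  expect_identical(nrow(cases), nrow(ctrls)) # 1:1
  expect_identical(table(cases$sex), table(ctrls$sex))
  expect_identical(table(cases$af), table(ctrls$af))
  ctrls_by_pair <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  expect_true(all(abs(cases$age - ctrls_by_pair$age) <= 2))
  expect_true(all(abs(cases$bmi - ctrls_by_pair$bmi) <= 1))
  # without replacement
  expect_false(any(duplicated(m$pairs$control_id)))
  # deterministic rerun
  m2 <- match_case_control(f$registry, matching_criteria())
  expect_identical(m$pairs, m2$pairs)
})

test_that("contingency construction and prevalence reproduce printed counts", {
  # 240 exposed with 37 events, 240 unexposed with 57 events
  grp <- data.frame(
    digoxin = rep(c(TRUE, FALSE), each = 240),
    fatty_liver = c(rep(TRUE, 37), rep(FALSE, 203),
                    rep(TRUE, 57), rep(FALSE, 183)))
  tab <- build_contingency(grp)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(37L, 203L, 57L, 183L))
  pv <- prevalence(tab)
  expect_identical(unname(pv), c(15.4, 23.8))
  # degenerate cases
  t0 <- contingency_2x2(0, 5, 0, 5)
  expect_identical(unname(prevalence(t0)), c(0, 0))
  t1 <- contingency_2x2(1, 0, 0, 0)
  expect_error(prevalence(t1), class = "liposcreen_input_error")
  expect_error(contingency_2x2(-1, 0, 0, 0),
               class = "liposcreen_input_error")
  bad <- grp
  bad$digoxin <- as.character(bad$digoxin)
  expect_error(build_contingency(bad), class = "liposcreen_input_error")
})

test_that("chi-square equals its closed form and the reference routine", {
  tab <- contingency_2x2(57, 183, 37, 203)
  res <- chi_square_2x2(tab)
  # closed-form oracle n(ad-bc)^2 / (row x col margins), by hand
  oracle <- 480 * (57 * 203 - 183 * 37)^2 / (240 * 240 * 94 * 386)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 5.29, tolerance = 0.01)
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(57, 37, 183, 203), 2), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  # proportions exactly equal -> statistic 0, p 1
  eq <- chi_square_2x2(contingency_2x2(10, 30, 20, 60))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 3, 4)),
               class = "liposcreen_degenerate_error")
})

test_that("continuity-corrected chi-square agrees with the exhaustive
           conditional permutation null on a tiny table", {
  tab <- contingency_2x2(4, 2, 2, 4) # n = 12, margins 6/6/6/6
  obs <- chi_square_2x2(tab, continuity = TRUE)
  # oracle: enumerate all tables with these margins (hypergeometric null)
  stat_of <- function(a) {
    b <- 6 - a; c <- 6 - a; d <- a
    chi_square_2x2(contingency_2x2(a, b, c, d))$statistic
  }
  s_obs <- chi_square_2x2(tab)$statistic
  support <- 0:6
  p_exact <- sum(dhyper(support, 6, 6, 6)[
    vapply(support, stat_of, numeric(1)) >= s_obs - 1e-12])
  expect_equal(obs$p, p_exact, tolerance = 0.05)
})

test_that("Mantel-Haenszel matches the reference implementation", {
  t1 <- contingency_2x2(12, 30, 20, 28, stratum = "s1")
  t2 <- contingency_2x2(5, 40, 12, 33, stratum = "s2")
  res <- mantel_haenszel(list(t1, t2))
  arr <- array(c(12, 20, 30, 28, 5, 12, 40, 33), dim = c(2, 2, 2))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  expect_equal(res$common_or, unname(ref$estimate), tolerance = 1e-9)
  # two identical strata give the same common OR as one
  res2 <- mantel_haenszel(list(t1, t1))
  expect_equal(res2$common_or, mantel_haenszel(list(t1))$common_or)
  # single stratum reduces to the crude OR
  expect_equal(mantel_haenszel(list(t1))$common_or,
               (12 * 28) / (30 * 20), tolerance = 1e-12)
  # a*d = b*c in every stratum -> statistic 0, OR 1
  null_t <- contingency_2x2(10, 20, 10, 20)
  res0 <- mantel_haenszel(list(null_t, null_t))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$common_or, 1)
  expect_error(mantel_haenszel(list(contingency_2x2(0, 0, 1, 1))),
               class = "liposcreen_degenerate_error")
})

test_that("covariate balance reproduces the Welch oracle and conventions", {
  df <- data.frame(g = rep(c("a", "b"), each = 3), x = c(1, 2, 3, 4, 5, 6))
  out <- covariate_balance(df, "g", "x")
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  ref <- stats::t.test(x ~ g, data = df)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(out$p, ref$p.value, tolerance = 1e-9)
  # identical degenerate groups -> p = 1 by convention
  dfe <- data.frame(g = rep(c("a", "b"), each = 3), x = rep(5, 6))
  expect_identical(covariate_balance(dfe, "g", "x")$p, 1)
  # n = 1 in a group errors
  df1 <- data.frame(g = c("a", "b", "b"), x = c(1, 2, 3))
  expect_error(covariate_balance(df1, "g", "x"),
               class = "liposcreen_input_error")
})
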