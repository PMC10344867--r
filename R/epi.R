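#' Apply nested case-control cohort filters
#'
#' Removes subjects with any required field missing (age, sex, BMI, AF,
#' digoxin, fatty liver), heart failure NYHA class II-IV, or age outside
#' 20-80 years. Exclusion reasons are counted with precedence
#' missing -> heart failure -> age (each subject counted once). When a
#' subject appears more than once and an `exam_date` column exists, the most
#' recent record is kept before filtering; otherwise the last record wins.
#'
#' @param registry a `registry` data.frame.
#' @param age_limits inclusive inclusion window in years (default 20-80).
#' @return list with `registry` (filtered) and `report`, a
#'   `cohort_filter_report` with fields `n_input, n_excluded_total,
#'   n_excluded_by_reason (missing, heart_failure, age), n_remaining,
#'   n_exposed_remaining`.
#' @export
apply_cohort_filters <- function(registry, age_limits = c(20, 80)) {
  req <- c("subject_id", "age", "sex", "bmi", "af", "digoxin", "fatty_liver")
  miss_cols <- setdiff(req, names(registry))
  if (length(miss_cols)) {
    stop_input("registry lacks required columns: ",
               paste(miss_cols, collapse = ", "))
  }
  for (nm in c("af", "digoxin", "fatty_liver")) {
    if (!is.logical(registry[[nm]])) {
      stop_input("registry field '", nm, "' must be logical")
    }
  }
  n_raw <- nrow(registry)
  # deduplicate: most recent exam per subject (last record as fallback)
  if (anyDuplicated(registry$subject_id)) {
    ord <- if ("exam_date" %in% names(registry)) {
      order(registry$subject_id, registry$exam_date)
    } else {
      seq_len(n_raw)
    }
    registry <- registry[ord, , drop = FALSE]
    registry <- registry[!duplicated(registry$subject_id,
                                     fromLast = TRUE), , drop = FALSE]
  }
  n_input <- nrow(registry)
  missing <- !complete.cases(registry[, c("age", "sex", "bmi", "af",
                                          "digoxin", "fatty_liver")])
  hf <- !missing & !is.na(registry$hf_nyha) & registry$hf_nyha >= 2
  age_out <- !missing & !hf &
    (registry$age < age_limits[1] | registry$age > age_limits[2])
  excl <- missing | hf | age_out
  kept <- registry[!excl, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("registry", "data.frame")
  report <- structure(list(
    n_input = n_input, n_excluded_total = sum(excl),
    n_excluded_by_reason = c(missing = sum(missing),
                             heart_failure = sum(hf), age = sum(age_out)),
    n_remaining = nrow(kept),
    n_exposed_remaining = sum(kept$digoxin)),
    class = "cohort_filter_report")
  list(registry = kept, report = report)
}

#' Matching criteria for 1:1 case-control selection
#'
#' @param exact_vars variables matched exactly (default sex and AF).
#' @param age_caliper maximum age difference, years (default 2).
#' @param bmi_caliper maximum BMI difference, kg/m2 (default 1).
#' @return a `matching_criteria` list (1:1, without replacement).
#' @export
matching_criteria <- function(exact_vars = c("sex", "af"),
                              age_caliper = 2, bmi_caliper = 1) {
  if (age_caliper <= 0 || bmi_caliper <= 0) {
    stop_input("calipers must be positive")
  }
  structure(list(exact_vars = exact_vars, age_caliper = age_caliper,
                 bmi_caliper = bmi_caliper),
            class = "matching_criteria")
}

#' 1:1 nearest-neighbour matching without replacement
#'
#' Cases (exposed subjects) are matched to unexposed controls exactly on the
#' exact variables and greedily on the normalised continuous distance
#' `|d_age|/age_caliper + |d_bmi|/bmi_caliper`, restricted to controls
#' within both calipers. Cases with the fewest eligible controls are matched
#' first (scarcity-first), ties in distance are broken by the lowest control
#' subject id, and each control is used at most once. Unmatched cases are
#' dropped and reported.
#'
#' @param registry a filtered `registry`.
#' @param criteria a [matching_criteria()].
#' @param seed integer seed (the algorithm is deterministic; the seed is
#'   accepted for interface uniformity and reserved for future stochastic
#'   tie-breaking).
#' @param exposure name of the logical exposure column (default "digoxin").
#' @return a `matched_cohort`: list with `pairs` (pair_id, case_id,
#'   control_id, distance), `cohort` (stacked matched registry rows with a
#'   `matched_group` column, "case" or "control") and `unmatched_cases`.
#' @export
match_case_control <- function(registry, criteria = matching_criteria(),
                               seed = 1L, exposure = "digoxin") {
  expo <- registry[[exposure]]
  if (is.null(expo)) stop_input("no exposure column '", exposure, "'")
  cases <- registry[expo, , drop = FALSE]
  ctrls <- registry[!expo, , drop = FALSE]
  if (!nrow(cases) || !nrow(ctrls)) {
    stop_input("exposed and unexposed pools must both be non-empty")
  }
  strat_key <- function(df) {
    do.call(paste, c(lapply(criteria$exact_vars, function(v) df[[v]]),
                     sep = "|"))
  }
  cases$.stratum <- strat_key(cases)
  ctrls$.stratum <- strat_key(ctrls)

  pair_case <- character(0); pair_ctrl <- character(0); pair_d <- numeric(0)
  unmatched <- character(0)
  for (s in unique(cases$.stratum)) {
    ca <- cases[cases$.stratum == s, , drop = FALSE]
    co <- ctrls[ctrls$.stratum == s, , drop = FALSE]
    if (!nrow(co)) {
      warning("no controls in stratum '", s, "'; skipping ", nrow(ca),
              " case(s)")
      unmatched <- c(unmatched, ca$subject_id)
      next
    }
    co <- co[order(co$subject_id), , drop = FALSE]
    avail <- rep(TRUE, nrow(co))
    # eligibility counts for scarcity-first ordering
    elig <- vapply(seq_len(nrow(ca)), function(i) {
      sum(abs(co$age - ca$age[i]) <= criteria$age_caliper &
            abs(co$bmi - ca$bmi[i]) <= criteria$bmi_caliper)
    }, numeric(1))
    for (i in order(elig, ca$subject_id)) {
      d_age <- abs(co$age - ca$age[i])
      d_bmi <- abs(co$bmi - ca$bmi[i])
      ok <- avail & d_age <= criteria$age_caliper &
        d_bmi <= criteria$bmi_caliper
      if (!any(ok)) {
        unmatched <- c(unmatched, ca$subject_id[i])
        next
      }
      d <- d_age / criteria$age_caliper + d_bmi / criteria$bmi_caliper
      d[!ok] <- Inf
      j <- which.min(d) # ties: lowest control id (co sorted by id)
      avail[j] <- FALSE
      pair_case <- c(pair_case, ca$subject_id[i])
      pair_ctrl <- c(pair_ctrl, co$subject_id[j])
      pair_d <- c(pair_d, d[j])
    }
  }
  pairs <- data.frame(pair_id = seq_along(pair_case), case_id = pair_case,
                      control_id = pair_ctrl, distance = pair_d,
                      stringsAsFactors = FALSE)
  reg_case <- registry[match(pairs$case_id, registry$subject_id), ,
                       drop = FALSE]
  reg_ctrl <- registry[match(pairs$control_id, registry$subject_id), ,
                       drop = FALSE]
  reg_case$matched_group <- rep("case", nrow(reg_case))
  reg_ctrl$matched_group <- rep("control", nrow(reg_ctrl))
  reg_case$pair_id <- pairs$pair_id
  reg_ctrl$pair_id <- pairs$pair_id
  cohort <- rbind(reg_case, reg_ctrl)
  rownames(cohort) <- NULL
  structure(list(pairs = pairs, cohort = cohort,
                 unmatched_cases = unmatched),
            class = "matched_cohort")
}

#' 2x2 contingency table
#'
#' Cell convention: `a` exposed & outcome-positive, `b` exposed &
#' outcome-negative, `c` unexposed & outcome-positive, `d` unexposed &
#' outcome-negative.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param stratum optional stratum label.
#' @return a `contingency_2x2` list.
#' @export
contingency_2x2 <- function(a, b, c, d, stratum = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("cell counts must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 stratum = stratum), class = "contingency_2x2")
}

#' Build a 2x2 table from subject-level data
#'
#' @param data data.frame with logical exposure and outcome columns (e.g. a
#'   matched cohort).
#' @param exposure,outcome column names.
#' @param stratum optional stratum label.
#' @return a [contingency_2x2()].
#' @export
build_contingency <- function(data, exposure = "digoxin",
                              outcome = "fatty_liver",
                              stratum = NA_character_) {
  e <- data[[exposure]]; o <- data[[outcome]]
  if (!is.logical(e) || !is.logical(o)) {
    stop_input("exposure and outcome must be logical columns")
  }
  contingency_2x2(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o),
                  stratum = stratum)
}

#' Outcome prevalence per exposure group
#'
#' @param table a [contingency_2x2()].
#' @param digits decimal places for the percentage (default 1, as reported
#'   in clinical tables).
#' @return named numeric, percentages: `exposed = 100 a/(a+b)`,
#'   `unexposed = 100 c/(c+d)`.
#' @export
prevalence <- function(table, digits = 1) {
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop_input("prevalence undefined for an empty exposure group")
  }
  c(exposed = round(100 * table$a / (table$a + table$b), digits),
    unexposed = round(100 * table$c / (table$c + table$d), digits))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optional Yates
#' continuity correction, p-value from the chi-square distribution with one
#' degree of freedom.
#'
#' @param table a [contingency_2x2()].
#' @param continuity apply the Yates correction (default FALSE).
#' @return list with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  m <- c(a + b, cc + d, a + cc, b + d)
  if (any(m == 0)) stop_degenerate("chi-square undefined: zero margin")
  num <- abs(a * d - b * cc)
  if (continuity) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(m)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Mantel-Haenszel test over stratified 2x2 tables
#'
#' Cochran-Mantel-Haenszel chi-square (continuity correction off by default)
#' and the Mantel-Haenszel common odds ratio
#' `sum(a d / n) / sum(b c / n)`, with a Robins-Breslow-Greenland standard
#' error of the log odds ratio.
#'
#' @param tables list of [contingency_2x2()] (>= 1 stratum).
#' @param continuity apply a 0.5 continuity correction to the CMH statistic.
#' @return list with `statistic`, `p`, `common_or`, `log_or_se`.
#' @export
mantel_haenszel <- function(tables, continuity = FALSE) {
  if (inherits(tables, "contingency_2x2")) tables <- list(tables)
  if (!length(tables)) stop_input("at least one stratum required")
  ok <- vapply(tables, function(t) {
    all(c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d) > 0)
  }, logical(1))
  if (!any(ok)) stop_degenerate("all strata degenerate (zero margins)")
  tables <- tables[ok]
  A <- vapply(tables, `[[`, numeric(1), "a")
  B <- vapply(tables, `[[`, numeric(1), "b")
  C <- vapply(tables, `[[`, numeric(1), "c")
  D <- vapply(tables, `[[`, numeric(1), "d")
  N <- A + B + C + D
  Ea <- (A + B) * (A + C) / N
  Va <- (A + B) * (C + D) * (A + C) * (B + D) / (N^2 * (N - 1))
  dev <- abs(sum(A) - sum(Ea))
  if (continuity) dev <- max(0, dev - 0.5)
  stat <- dev^2 / sum(Va)
  R <- A * D / N; S <- B * C / N
  common_or <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (A + D) / N; Q <- (B + C) / N
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       common_or = common_or, log_or_se = sqrt(var_log))
}

#' Covariate balance between two groups
#'
#' Mean and SD per group plus a two-sided unpaired t-test (Welch by default)
#' for each continuous variable, as reported in baseline-characteristics
#' tables. When both groups have zero variance and equal means the p-value
#' is 1 by convention.
#'
#' @param data data.frame holding the variables and a group column.
#' @param group name of a two-level grouping column.
#' @param variables character vector of numeric columns to compare.
#' @param equal_variance use the pooled-variance t-test instead of Welch.
#' @return data.frame: one row per variable with group means, SDs, the t
#'   statistic and p-value.
#' @export
covariate_balance <- function(data, group, variables,
                              equal_variance = FALSE) {
  g <- data[[group]]
  lev <- unique(g)
  if (length(lev) != 2) stop_input("group column must have exactly 2 levels")
  rows <- lapply(variables, function(v) {
    x <- data[[v]][g == lev[1]]
    y <- data[[v]][g == lev[2]]
    tt <- welch_t(x, y, equal_variance)
    data.frame(variable = v,
               mean_1 = mean(x), sd_1 = sd(x),
               mean_2 = mean(y), sd_2 = sd(y),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lev
  out
}

welch_t <- function(x, y, equal_variance = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop_input("each group needs >= 2 observations")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    stop_degenerate("zero variance in both groups with unequal means")
  }
  if (equal_variance) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, p = 2 * pt(-abs(t), df))
}

#' Stratified 2x2 tables from a matched cohort
#'
#' Builds one contingency table per combination of the stratification
#' variables (default: the exact-matching cells, sex x AF), dropping strata
#' with zero margins from downstream Mantel-Haenszel pooling.
#'
#' @param cohort subject-level data.frame (e.g. `matched_cohort$cohort`).
#' @param strata_vars columns defining strata.
#' @param exposure,outcome logical column names.
#' @return list of [contingency_2x2()].
#' @export
stratified_tables <- function(cohort, strata_vars = c("sex", "af"),
                              exposure = "digoxin",
                              outcome = "fatty_liver") {
  key <- do.call(paste, c(lapply(strata_vars, function(v) cohort[[v]]),
                          sep = "|"))
  lapply(unique(key), function(s) {
    build_contingency(cohort[key == s, , drop = FALSE], exposure, outcome,
                      stratum = s)
  })
}
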