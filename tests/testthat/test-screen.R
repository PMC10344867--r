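quant_stub <- function(scores, wells = NULL, role = "compound",
                       cells = 100, plate = "P01") {
  n <- length(scores)
  if (is.null(wells)) wells <- sprintf("A%02d", seq_len(n))
  data.frame(plate_id = plate, row = 1, col = seq_len(n), well = wells,
             role = role, compound_id = ifelse(role == "compound",
                                               sprintf("C%03d", seq_len(n)),
                                               NA_character_),
             cell_count = cells, mcherry_area_px = 10, gfp_total = 0,
             mcherry_total = 0, score_raw = scores, flags = "",
             stringsAsFactors = FALSE)
}

test_that("DMSO conversion subtracts/divides positionally and validates", {
  q <- quant_stub(c(250, 100, 0))
  d <- quant_stub(c(100, 100, 100))
  conv <- dmso_convert(q, d)
  expect_identical(conv$score_converted, c(150, 0, -100))
  # plate identical to its own DMSO plate -> all zeros
  self <- dmso_convert(d, d)
  expect_true(all(self$score_converted == 0))
  # divide mode
  conv2 <- dmso_convert(q, d, screen_config(dmso_correction_mode = "divide"))
  expect_identical(conv2$score_converted, c(2.5, 1, 0))
  d0 <- quant_stub(c(100, 0, 100))
  expect_error(dmso_convert(q, d0,
                            screen_config(dmso_correction_mode = "divide")),
               "A02", class = "liposcreen_degenerate_error")
  # missing well position
  expect_error(dmso_convert(q, d[-2, ]), "A02",
               class = "liposcreen_input_error")
})

test_that("an additive positional gradient cancels exactly under subtraction", {
  base_scores <- c(5, -3, 12, 0, 7, 2, -1, 4)
  dmso_scores <- c(1, 2, 0, -1, 3, 1, 0, 2)
  gradient <- seq(0, 70, by = 10) # same well-position field on both plates
  q_clean <- quant_stub(base_scores)
  d_clean <- quant_stub(dmso_scores)
  q_art <- quant_stub(base_scores + gradient)
  d_art <- quant_stub(dmso_scores + gradient)
  expect_identical(dmso_convert(q_art, d_art)$score_converted,
                   dmso_convert(q_clean, d_clean)$score_converted)
})

test_that("robust Z matches the hand-computed oracle and its invariances", {
  x <- c(10, 12, 11, 9, 50)
  z <- robust_z(x)
  # median 11, MAD 1 -> robust SD 1.4826; Z(50) = 39/1.4826
  expect_equal(z[5], 39 / 1.4826, tolerance = 1e-12)
  expect_equal(z[3], 0)
  expect_equal(robust_z(c(11, x))[1], 0) # any value at the median maps to 0
  # location/scale invariance
  expect_equal(robust_z(3.7 * x - 42), z, tolerance = 1e-12)
  # median of Z over samples is 0
  y <- with_seed_local(4, rnorm(999))
  expect_equal(median(robust_z(y)), 0, tolerance = 1e-12)
  expect_error(robust_z(rep(5, 10)), class = "liposcreen_degenerate_error")
  expect_error(robust_z(c(1, 2)), class = "liposcreen_input_error")
})

test_that("toxicity gate uses the DMSO median with a strict 80% cut", {
  cfg <- screen_config()
  q <- quant_stub(rep(0, 3))
  q$cell_count <- c(80, 79, 100)
  expect_identical(toxicity_filter(q, c(100, 100, 100), cfg),
                   c(FALSE, TRUE, FALSE)) # exactly 80% retained
  q2 <- quant_stub(0)
  q2$cell_count <- 79
  expect_true(toxicity_filter(q2, c(100, 100, 120), cfg)) # reference 100
  expect_error(toxicity_filter(q, numeric(0), cfg),
               class = "liposcreen_input_error")
})

test_that("hit calling is strict in Z, excludes toxic wells and sorts", {
  scr <- quant_stub(rep(0, 4))
  scr$robust_z <- c(3.0, 3.01, 8, 5)
  scr$toxic <- c(FALSE, FALSE, TRUE, FALSE)
  out <- call_hits(scr)
  expect_identical(out$hit, c(FALSE, TRUE, FALSE, TRUE))
  hits <- attr(out, "hits")
  expect_identical(hits$well, c("A04", "A02")) # descending Z
  expect_error(call_hits(quant_stub(0)), class = "liposcreen_input_error")
})

test_that("fold change is a ratio of medians with an explicit undefined case", {
  expect_identical(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(fold_change(c(400, 500, 600), c(9, 10, 11)), 50)
  fc <- fold_change(c(1, 2), c(-1, 0, 1))
  expect_true(is.na(fc))
  expect_identical(attr(fc, "flag"), "UNDEFINED_FOLD")
  expect_error(fold_change(numeric(0), 1), class = "liposcreen_input_error")
})

test_that("score_screen composes gates and Z over an image-based screen", {
  fs <- fixture_screen()
  scr <- fs$table
  truth <- fs$sim$truth_all
  act <- truth$compound_id[truth$quench_fraction > 0]
  tox <- truth$compound_id[truth$toxicity_factor < 1]
  expect_identical(nrow(scr), sum(truth$role == "compound"))
  # all spiked actives called, no toxic well among hits
  expect_true(all(scr$hit[scr$compound_id %in% act]))
  expect_true(!any(scr$hit & scr$toxic))
  expect_true(all(scr$toxic[scr$compound_id %in% tox]))
  s <- attr(scr, "summary")
  expect_identical(s$n_compound, 60L)
  expect_gte(s$n_hits, length(act))
})
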