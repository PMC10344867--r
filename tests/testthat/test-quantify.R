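test_that("blank wells count zero nuclei and segment an empty mask", {
  img <- blank_image(noise_sd = 0)
  expect_identical(count_nuclei(img), 0L)
  expect_false(any(segment_mcherry_mask(img)))
  img_n <- blank_image(noise_sd = 8, seed = 3)
  expect_identical(count_nuclei(img_n), 0L)
  expect_false(any(segment_mcherry_mask(img_n)))
})

test_that("nucleus counting recovers ground truth on rendered wells", {
  # noiseless: exact
  w0 <- fixture_well(n_cells = 10, noise_sd = 0, channel_cv = 0)
  expect_identical(count_nuclei(w0$image), 10L)
  # default noise, grid-separated nuclei: within +/- 1 of 45
  wN <- fixture_well(n_cells = 45, seed = 13)
  expect_lte(abs(count_nuclei(wN$image) - 45), 1)
  # missing channel errors by name
  img <- w0$image
  img$channels$BFP <- NULL
  expect_error(count_nuclei(img), "BFP", class = "liposcreen_input_error")
  expect_error(segment_mcherry_mask(list(channels = list())), "mCherry",
               class = "liposcreen_input_error")
})

test_that("fluorescence integration matches hand sums and is mask-local", {
  gfp <- matrix(0, 4, 4); gfp[1, 1:4] <- c(1, 2, 3, 4)
  mch <- matrix(0, 4, 4); mch[1, 1:4] <- 5
  img <- structure(list(channels = list(BFP = matrix(0, 4, 4), GFP = gfp,
                                        mCherry = mch)),
                   class = "well_image")
  mask <- matrix(FALSE, 4, 4); mask[1, 1:4] <- TRUE
  tot <- integrate_fluorescence(img, mask)
  expect_identical(tot$gfp_total, 10)
  expect_identical(tot$mcherry_total, 20)
  expect_identical(tot$area_px, 4L)
  # empty mask
  tot0 <- integrate_fluorescence(img, matrix(FALSE, 4, 4))
  expect_identical(unlist(tot0), c(gfp_total = 0, mcherry_total = 0,
                                   area_px = 0))
  # signal outside the mask never changes totals
  img2 <- img
  img2$channels$GFP[3, 3] <- 1e6
  expect_identical(integrate_fluorescence(img2, mask)$gfp_total, 10)
  expect_error(integrate_fluorescence(img, matrix(FALSE, 2, 2)),
               "shape", class = "liposcreen_input_error")
})

test_that("lipophagy score arithmetic, sign and failure modes", {
  expect_identical(lipophagy_score(2000, 5000, 10), 300)
  expect_identical(lipophagy_score(100, 50, 5), -10)
  expect_identical(lipophagy_score(7, 7, 3), 0)
  expect_error(lipophagy_score(1, 2, 0), "NO_CELLS",
               class = "liposcreen_no_cells")
  expect_error(lipophagy_score(1, 2, -1), class = "liposcreen_input_error")
})

test_that("plate quantification flags, orders and reproduces", {
  lay <- make_plate_layout(2, 2, seed = 1, n_rows = 2, n_cols = 2,
                           plate_id = "T")
  blanks <- setNames(lapply(1:4, function(i) blank_image(seed = i)),
                     lay$well)
  q <- quantify_plate(blanks, lay)
  expect_true(all(grepl("EMPTY_MASK", q$flags)))
  expect_true(all(grepl("NO_CELLS", q$flags)))
  expect_true(all(q$score_raw == 0))
  # row-major traversal order
  expect_identical(q$well, lay$well[lay$role != "empty"])
  # determinism
  expect_identical(q, quantify_plate(blanks, lay))
  # missing image lists wells
  expect_error(quantify_plate(blanks[-2], lay), lay$well[2],
               class = "liposcreen_input_error")
})

test_that("quenched wells score higher than unquenched wells", {
  w0 <- fixture_well(quench = 0, seed = 21)
  w9 <- fixture_well(quench = 0.9, seed = 21)
  seg <- segmentation_params()
  score <- function(img) {
    m <- segment_mcherry_mask(img, seg)
    tot <- integrate_fluorescence(img, m)
    lipophagy_score(tot$gfp_total, tot$mcherry_total,
                    count_nuclei(img, seg))
  }
  expect_gt(score(w9$image), score(w0$image))
})

test_that("mask area is stable against default noise (ground-truth oracle)", {
  w_noisy <- fixture_well(n_cells = 20, seed = 31)
  truth <- w_noisy$truth
  p0 <- w_noisy$params
  p0$noise_sd <- 0
  w0 <- render_well_image(truth, p0) # identical scene, no noise
  a0 <- sum(segment_mcherry_mask(w0))
  aN <- sum(segment_mcherry_mask(w_noisy$image))
  expect_lt(abs(aN - a0) / a0, 0.10)
})
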