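# Shared fixtures, built once per test run. Image tests use 128x128 wells
# (49-nucleus grid capacity) to keep the suite fast; the acceptance tests
# state their own sizes.

fx <- new.env()

small_params <- function(...) {
  imaging_params(image_size = c(128L, 128L), rng_seed = 42L, ...)
}

# one rendered well with known truth
fixture_well <- function(n_cells = 10, quench = 0, noise_sd = 8,
                         channel_cv = 0.05, seed = 42L, row = 2, col = 3) {
  truth <- list(plate_id = "P01", row = row, col = col,
                true_cell_count = n_cells, quench_fraction = quench,
                toxicity_factor = 1, droplet_density = 3)
  p <- imaging_params(image_size = c(128L, 128L), noise_sd = noise_sd,
                      channel_cv = channel_cv, rng_seed = seed)
  list(truth = truth, params = p, image = render_well_image(truth, p))
}

# a quantified small screen shared by screen-statistics tests
fixture_screen <- function() {
  if (!is.null(fx$screen)) return(fx$screen)
  sim <- simulate_screen_inputs(
    n_compounds = 60, n_actives = 4, n_toxic = 2, seed = 11,
    params = small_params(), compounds_per_plate = 60,
    n_dmso_per_plate = 12, mean_cells = 25)
  seg <- segmentation_params()
  quants <- lapply(sim$plates, function(p) {
    quantify_plate(p$images, p$layout, seg)
  })
  dmso_quant <- quantify_plate(sim$dmso_plate$images, sim$dmso_plate$layout,
                               seg)
  fx$screen <- list(sim = sim, quants = quants, dmso_quant = dmso_quant,
                    table = score_screen(quants, dmso_quant))
  fx$screen
}

# synthetic blank image (uniform background plus optional noise)
blank_image <- function(H = 64, W = 64, bg = 100, noise_sd = 0, seed = 1) {
  ch <- with_seed_local(seed, {
    lapply(1:3, function(i) {
      m <- matrix(bg, H, W)
      if (noise_sd > 0) m <- m + matrix(rnorm(H * W, 0, noise_sd), H, W)
      round(m)
    })
  })
  structure(list(channels = list(BFP = ch[[1]], GFP = ch[[2]],
                                 mCherry = ch[[3]]),
                 well = "A01", plate_id = "BLANK", row = 1, col = 1),
            class = "well_image")
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# toy registry used by the cohort-filter oracle tests: 10 subjects of which
# 2 have NYHA III, 1 is aged 85 and 1 has missing BMI -> 6 remain
toy_registry <- function() {
  data.frame(
    subject_id = sprintf("T%02d", 1:10),
    age = c(50, 60, 85, 40, 55, 65, 70, 45, 62, 58),
    sex = rep(c("M", "F"), 5),
    bmi = c(22, 24, 23, NA, 25, 21, 26, 22, 24, 23),
    af = rep(c(TRUE, FALSE), 5),
    hf_nyha = c(NA, 3L, NA, NA, 3L, NA, NA, NA, NA, NA),
    digoxin = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE),
    fatty_liver = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                    FALSE, FALSE),
    stringsAsFactors = FALSE)
}
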