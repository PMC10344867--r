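#' Imaging parameters for the synthetic microscope
#'
#' Describes how a well is rendered: raster size and bit depth, background
#' and read-noise levels, blob geometry for nuclei and lipid droplets,
#' fluorophore amplitudes, per-well channel gain variation, and an additive
#' per-well position artifact (smooth row/column gradients over the plate).
#'
#' Blob geometry: `nucleus_radius_px` and `droplet_radius_px` are the visible
#' blob radii; blobs are isotropic Gaussians with `sigma = 0.4 * radius`, so
#' the visible extent (~2.5 sigma) matches the stated radius. Nuclei are
#' placed on a jittered grid with pitch `6 * nucleus_radius_px` and jitter
#' `+/- nucleus_radius_px`, guaranteeing a minimum separation of four radii
#' so that connected-component counting is well posed.
#'
#' `channel_cv` is the well-to-well lognormal CV of each fluorescence
#' channel's gain. It is the dominant null variation of the lipophagy score:
#' GFP and mCherry droplet images share geometry exactly, so without gain
#' variation the score's null spread would collapse to read noise alone.
#'
#' @param image_size integer c(height, width) in pixels.
#' @param bit_depth 8 or 16.
#' @param background_level additive background, counts.
#' @param noise_sd Gaussian read-noise SD, counts (0 = noiseless).
#' @param poisson_noise add Poisson shot noise (off by default so tests are
#'   exactly reproducible under a seed).
#' @param nucleus_radius_px,droplet_radius_px blob radii, pixels.
#' @param nucleus_amp nuclear TagBFP peak amplitude, counts.
#' @param droplet_gfp_amp,droplet_mcherry_amp droplet peak amplitudes, counts.
#' @param channel_cv per-well lognormal CV of each channel gain.
#' @param droplet_amp_cv per-droplet lognormal size/brightness CV (shared
#'   between GFP and mCherry, which image the same droplet).
#' @param position_artifact list with `row_amp`, `col_amp` (counts, amplitude
#'   of the additive gradient across the plate) and `channels` (which
#'   channels receive it).
#' @param rng_seed integer; every well derives its own substream from it.
#' @return an `imaging_params` list.
#' @export
imaging_params <- function(image_size = c(256L, 256L), bit_depth = 16L,
                           background_level = 100, noise_sd = 8,
                           poisson_noise = FALSE,
                           nucleus_radius_px = 3, droplet_radius_px = 1.5,
                           nucleus_amp = 3000, droplet_gfp_amp = 2000,
                           droplet_mcherry_amp = 2000,
                           channel_cv = 0.05, droplet_amp_cv = 0.2,
                           position_artifact = list(row_amp = 0, col_amp = 0,
                             channels = c("BFP", "GFP", "mCherry")),
                           rng_seed = 1L) {
  if (!bit_depth %in% c(8L, 16L)) stop_input("bit_depth must be 8 or 16")
  if (any(image_size < 1)) stop_input("image_size must be positive")
  if (noise_sd < 0 || background_level < 0) {
    stop_input("noise and background must be non-negative")
  }
  pa <- position_artifact
  if (is.null(pa$row_amp)) pa$row_amp <- 0
  if (is.null(pa$col_amp)) pa$col_amp <- 0
  if (is.null(pa$channels)) pa$channels <- c("BFP", "GFP", "mCherry")
  if (pa$row_amp < 0 || pa$col_amp < 0) {
    stop_input("artifact amplitudes must be non-negative")
  }
  structure(list(
    image_size = as.integer(image_size), bit_depth = as.integer(bit_depth),
    background_level = background_level, noise_sd = noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    nucleus_radius_px = nucleus_radius_px,
    droplet_radius_px = droplet_radius_px,
    nucleus_amp = nucleus_amp, droplet_gfp_amp = droplet_gfp_amp,
    droplet_mcherry_amp = droplet_mcherry_amp,
    channel_cv = channel_cv, droplet_amp_cv = droplet_amp_cv,
    position_artifact = pa, rng_seed = as.integer(rng_seed)),
    class = "imaging_params")
}

# Jittered-grid nucleus placement: pitch 6r, jitter +/- r, so centres are
# >= 4r apart. Returns the grid capacity and a sampler of n positions.
nucleus_grid <- function(H, W, radius) {
  pitch <- 6 * radius
  margin <- 2 * radius + 1
  ys <- seq(margin, H - margin, by = pitch)
  xs <- seq(margin, W - margin, by = pitch)
  list(capacity = length(ys) * length(xs), ys = ys, xs = xs)
}

#' Render one well of the lipophagy reporter assay
#'
#' Produces a 3-channel image (BFP nuclei, GFP and mCherry lipid droplets).
#' The number of rendered nuclei is `round(true_cell_count * toxicity_factor)`.
#' Droplets are placed in an annulus around their parent nucleus and are
#' identical in both fluorescence channels except that the GFP amplitude is
#' scaled by `1 - quench_fraction` (GFP is quenched at lysosomal pH while
#' mCherry persists). The scene (placement, gains) and the noise use separate
#' derived seeds, so setting `noise_sd = 0` reproduces the identical scene
#' without noise.
#'
#' @param truth one row of a `screen_truth` table (or a list with fields
#'   `row`, `col`, `true_cell_count`, `quench_fraction`, `toxicity_factor`,
#'   `droplet_density`).
#' @param params an [imaging_params()] object.
#' @param plate_dims c(n_rows, n_cols) of the plate, for the position
#'   artifact gradient (default 16 x 24).
#' @return a `well_image`: list with `channels` (named list of H x W
#'   matrices BFP/GFP/mCherry), `well`, `plate_id`, and attribute `scene`
#'   holding ground-truth blob coordinates.
#' @export
render_well_image <- function(truth, params, plate_dims = c(16L, 24L)) {
  stopifnot(inherits(params, "imaging_params"))
  H <- params$image_size[1]; W <- params$image_size[2]
  if (H < 1 || W < 1) stop_input("zero-size image")
  n_eff <- as.integer(round(truth$true_cell_count * truth$toxicity_factor))
  grid <- nucleus_grid(H, W, params$nucleus_radius_px)
  if (n_eff > grid$capacity) {
    stop_input(sprintf(
      "cannot place %d nuclei in a %dx%d image (grid capacity %d)",
      n_eff, H, W, grid$capacity))
  }
  widx <- (truth$row - 1) * 1000 + truth$col
  sig_n <- 0.4 * params$nucleus_radius_px
  sig_d <- 0.4 * params$droplet_radius_px

  scene <- with_seed(derive_seed(params$rng_seed, widx), {
    slots <- if (n_eff > 0) sample.int(grid$capacity, n_eff) else integer(0)
    gy <- grid$ys[((slots - 1) %% length(grid$ys)) + 1]
    gx <- grid$xs[((slots - 1) %/% length(grid$ys)) + 1]
    ny <- gy + runif(n_eff, -params$nucleus_radius_px,
                     params$nucleus_radius_px)
    nx <- gx + runif(n_eff, -params$nucleus_radius_px,
                     params$nucleus_radius_px)
    ndrop <- if (n_eff > 0) rpois(n_eff, truth$droplet_density) else integer(0)
    k <- sum(ndrop)
    parent <- rep(seq_len(n_eff), ndrop)
    ang <- runif(k, 0, 2 * pi)
    rad <- runif(k, 1, 2) * params$nucleus_radius_px
    dy <- pmin(pmax(ny[parent] + rad * sin(ang), 1), H)
    dx <- pmin(pmax(nx[parent] + rad * cos(ang), 1), W)
    dsize <- rlnorm(k, -params$droplet_amp_cv^2 / 2, params$droplet_amp_cv)
    gain <- rlnorm(3, -params$channel_cv^2 / 2, params$channel_cv)
    list(ny = ny, nx = nx, dy = dy, dx = dx, dsize = dsize,
         gain_bfp = gain[1], gain_gfp = gain[2], gain_mch = gain[3])
  })

  bg <- params$background_level
  bfp <- .cpp_render_blobs(H, W, scene$ny, scene$nx,
                           rep(params$nucleus_amp * scene$gain_bfp,
                               length(scene$ny)), sig_n) + bg
  gfp <- .cpp_render_blobs(H, W, scene$dy, scene$dx,
                           params$droplet_gfp_amp * scene$gain_gfp *
                             (1 - truth$quench_fraction) * scene$dsize,
                           sig_d) + bg
  mch <- .cpp_render_blobs(H, W, scene$dy, scene$dx,
                           params$droplet_mcherry_amp * scene$gain_mch *
                             scene$dsize, sig_d) + bg
  ch <- list(BFP = bfp, GFP = gfp, mCherry = mch)

  pa <- params$position_artifact
  if (pa$row_amp > 0 || pa$col_amp > 0) {
    off <- pa$row_amp * (truth$row - 1) / max(1, plate_dims[1] - 1) +
           pa$col_amp * (truth$col - 1) / max(1, plate_dims[2] - 1)
    for (nm in intersect(pa$channels, names(ch))) ch[[nm]] <- ch[[nm]] + off
  }

  if (params$noise_sd > 0 || params$poisson_noise) {
    ch <- with_seed(derive_seed(params$rng_seed + 7L, widx), {
      lapply(ch, function(m) {
        if (params$poisson_noise) {
          m <- matrix(rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
        }
        if (params$noise_sd > 0) {
          m <- m + matrix(rnorm(length(m), 0, params$noise_sd),
                          nrow(m), ncol(m))
        }
        m
      })
    })
  }
  maxv <- 2^params$bit_depth - 1
  ch <- lapply(ch, function(m) pmin(pmax(round(m), 0), maxv))

  structure(list(channels = ch, well = well_name(truth$row, truth$col),
                 plate_id = truth$plate_id %||% "P01",
                 row = truth$row, col = truth$col),
            scene = scene, class = "well_image")
}

#' Render all wells of a ground-truth table
#'
#' @param truth a `screen_truth` table.
#' @param params an [imaging_params()].
#' @return named list of `well_image` objects keyed by well address.
#' @export
render_plate_images <- function(truth, params) {
  dims <- c(attr(truth, "n_rows") %||% 16L, attr(truth, "n_cols") %||% 24L)
  imgs <- lapply(seq_len(nrow(truth)), function(i) {
    render_well_image(truth[i, ], params, plate_dims = dims)
  })
  names(imgs) <- truth$well
  imgs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
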