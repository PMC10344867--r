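#' Segmentation parameters for per-well quantification
#'
#' Thresholds are robust background statistics computed on the smoothed
#' channel: `median + k * max(MAD, mad_floor)`, where MAD is the
#' Gaussian-consistent median absolute deviation ([stats::mad()], constant
#' 1.4826). The `mad_floor` (in counts) guards the degenerate case of
#' noiseless or blank rasters, where the MAD collapses to zero and a bare
#' median threshold would select every pixel of a Gaussian tail.
#'
#' @param k_nuc threshold multiplier for the nuclear (BFP) channel.
#' @param k_mch threshold multiplier for the mCherry channel.
#' @param min_blob_area_px minimum connected-component area kept, pixels.
#' @param smoothing_radius Gaussian smoothing sigma, pixels.
#' @param mad_floor lower bound on the MAD scale estimate, counts.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(k_nuc = 6, k_mch = 4, min_blob_area_px = 4L,
                                smoothing_radius = 1, mad_floor = 2) {
  if (k_nuc <= 0 || k_mch <= 0) stop_input("threshold multipliers must be > 0")
  if (min_blob_area_px < 1) stop_input("min_blob_area_px must be >= 1")
  structure(list(k_nuc = k_nuc, k_mch = k_mch,
                 min_blob_area_px = as.integer(min_blob_area_px),
                 smoothing_radius = smoothing_radius, mad_floor = mad_floor),
            class = "segmentation_params")
}

get_channel <- function(image, name) {
  ch <- image$channels[[name]]
  if (is.null(ch)) stop_input("missing channel '", name, "' in well image")
  ch
}

robust_threshold_mask <- function(channel, k, params) {
  sm <- .cpp_gauss_blur(channel, params$smoothing_radius)
  thr <- median(sm) + k * max(mad(sm), params$mad_floor)
  sm > thr
}

drop_small_components <- function(mask, min_area) {
  if (!any(mask)) return(list(mask = mask, n = 0L))
  lab <- .cpp_label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  list(mask = matrix(lab %in% keep, nrow(mask), ncol(mask)),
       n = length(keep))
}

#' Count TagBFP-positive nuclei in a well image
#'
#' Connected components of the smoothed BFP channel above the robust
#' background threshold, with components smaller than `min_blob_area_px`
#' discarded, are counted as cells.
#'
#' @param image a `well_image`.
#' @param params a [segmentation_params()].
#' @return integer nucleus count.
#' @export
count_nuclei <- function(image, params = segmentation_params()) {
  ch <- get_channel(image, "BFP")
  mask <- robust_threshold_mask(ch, params$k_nuc, params)
  drop_small_components(mask, params$min_blob_area_px)$n
}

#' Segment the mCherry-positive area of a well image
#'
#' @inheritParams count_nuclei
#' @return logical H x W mask of mCherry-positive pixels.
#' @export
segment_mcherry_mask <- function(image, params = segmentation_params()) {
  ch <- get_channel(image, "mCherry")
  mask <- robust_threshold_mask(ch, params$k_mch, params)
  drop_small_components(mask, params$min_blob_area_px)$mask
}

#' Integrate GFP and mCherry fluorescence over a mask
#'
#' @param image a `well_image`.
#' @param mask logical matrix matching the channel shape.
#' @return list with `gfp_total`, `mcherry_total`, `area_px`.
#' @export
integrate_fluorescence <- function(image, mask) {
  gfp <- get_channel(image, "GFP")
  mch <- get_channel(image, "mCherry")
  if (!identical(dim(mask), dim(gfp))) {
    stop_input("mask shape ", paste(dim(mask), collapse = "x"),
               " does not match channel shape ",
               paste(dim(gfp), collapse = "x"))
  }
  list(gfp_total = sum(gfp[mask]), mcherry_total = sum(mch[mask]),
       area_px = sum(mask))
}

#' Lipophagy score of a well
#'
#' The per-well lipophagy readout: total mCherry fluorescence minus total GFP
#' fluorescence within the mCherry-positive area, divided by the cell number.
#' Negative values are legitimate (a well whose GFP exceeds mCherry). A zero
#' cell count is an assay failure and raises an error rather than returning a
#' silent zero.
#'
#' @param gfp_total,mcherry_total integrated fluorescence over the
#'   mCherry-positive mask.
#' @param cell_count nuclei counted in the same well.
#' @return the score (score units per cell).
#' @examples
#' lipophagy_score(2000, 5000, 10) # 300
#' @export
lipophagy_score <- function(gfp_total, mcherry_total, cell_count) {
  if (cell_count < 0) stop_input("cell_count must be >= 0")
  if (cell_count == 0) {
    stop(structure(class = c("liposcreen_no_cells", "liposcreen_input_error",
                             "error", "condition"),
                   list(message = "NO_CELLS: cell count is zero; well is unscoreable",
                        call = sys.call())))
  }
  (mcherry_total - gfp_total) / cell_count
}

#' Quantify every non-empty well of a plate
#'
#' Runs nucleus counting, mCherry segmentation, fluorescence integration and
#' scoring for each well, in the layout's row-major order. Wells with an
#' empty mCherry mask score 0 and are flagged `EMPTY_MASK` (a compound that
#' abolishes droplets is meaningful); wells with zero nuclei are flagged
#' `NO_CELLS` and score `NA` (assay failure).
#'
#' @param images named list of `well_image`, keyed by well address; or a
#'   directory containing `{plate}_{well}.tif` files.
#' @param layout a `plate_layout`.
#' @param params a [segmentation_params()].
#' @return a `well_quant` data.frame with columns `plate_id,row,col,well,
#'   role,compound_id,cell_count,mcherry_area_px,gfp_total,mcherry_total,
#'   score_raw,flags`.
#' @export
quantify_plate <- function(images, layout, params = segmentation_params()) {
  wells <- layout[layout$role != "empty", , drop = FALSE]
  if (is.character(images) && length(images) == 1L) {
    dir <- images
    paths <- file.path(dir, well_tiff_name(wells$plate_id, wells$row,
                                           wells$col))
    missing <- wells$well[!file.exists(paths)]
    if (length(missing)) {
      stop_input("missing image files for wells: ",
                 paste(missing, collapse = ", "))
    }
    images <- lapply(paths, read_well_tiff)
    names(images) <- wells$well
  }
  missing <- setdiff(wells$well, names(images))
  if (length(missing)) {
    stop_input("missing images for wells: ", paste(missing, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(wells)), function(i) {
    quantify_one_well(images[[wells$well[i]]], params)
  })
  out <- cbind(wells[, c("plate_id", "row", "col", "well", "role",
                         "compound_id")], do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("well_quant", "data.frame")
  out
}

#' Expected robust scale of smoothed read noise
#'
#' Gaussian smoothing with sigma `smoothing_radius` attenuates white read
#' noise of standard deviation `noise_sd` by approximately
#' `1 / (2 * smoothing_radius * sqrt(pi))`. When a ground-truth mask is
#' computed from a noiseless render, the segmentation's MAD estimate
#' collapses, so comparing against a noisy measurement requires pinning the
#' noiseless threshold at this expected noise scale (via `mad_floor`);
#' otherwise the two masks are cut at systematically different levels.
#'
#' @param noise_sd read-noise SD of the raster, counts.
#' @param smoothing_radius Gaussian smoothing sigma, pixels.
#' @return expected SD (= robust MAD scale) of the smoothed noise, counts.
#' @export
expected_smoothed_noise_sd <- function(noise_sd, smoothing_radius) {
  if (smoothing_radius <= 0) return(noise_sd)
  noise_sd / (2 * smoothing_radius * sqrt(pi))
}

# Quantify a single well image into one row of the well_quant table.
quantify_one_well <- function(img, params) {
  n <- count_nuclei(img, params)
  mask <- segment_mcherry_mask(img, params)
  tot <- integrate_fluorescence(img, mask)
  flags <- character(0)
  if (tot$area_px == 0) flags <- c(flags, "EMPTY_MASK")
  if (n == 0) flags <- c(flags, "NO_CELLS")
  score <- if (tot$area_px == 0) 0
           else if (n == 0) NA_real_
           else lipophagy_score(tot$gfp_total, tot$mcherry_total, n)
  data.frame(cell_count = n, mcherry_area_px = tot$area_px,
             gfp_total = tot$gfp_total, mcherry_total = tot$mcherry_total,
             score_raw = score, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write a per-well quantification table as TSV
#' @param quant a `well_quant` table.
#' @param path output path.
#' @export
write_quant_tsv <- function(quant, path) {
  df <- quant
  df$row <- LETTERS[df$row]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
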