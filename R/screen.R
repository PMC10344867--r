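#' Screening statistics configuration
#'
#' @param hit_z_threshold robust Z above which a non-toxic compound is a hit
#'   (strict inequality, default 3).
#' @param toxicity_fraction fraction of the DMSO reference cell number below
#'   which a well is toxic (strict inequality, default 0.80).
#' @param dmso_correction_mode `"subtract"` (default) or `"divide"`.
#' @param robust_scale_constant Gaussian-consistency constant multiplying the
#'   MAD (default 1.4826).
#' @param pool_plates compute robust Z over all compound wells pooled across
#'   plates (default TRUE) rather than per plate.
#' @return a `screen_config` list.
#' @export
screen_config <- function(hit_z_threshold = 3, toxicity_fraction = 0.80,
                          dmso_correction_mode = c("subtract", "divide"),
                          robust_scale_constant = 1.4826,
                          pool_plates = TRUE) {
  if (hit_z_threshold <= 0 || toxicity_fraction <= 0) {
    stop_input("thresholds must be positive")
  }
  structure(list(hit_z_threshold = hit_z_threshold,
                 toxicity_fraction = toxicity_fraction,
                 dmso_correction_mode = match.arg(dmso_correction_mode),
                 robust_scale_constant = robust_scale_constant,
                 pool_plates = isTRUE(pool_plates)),
            class = "screen_config")
}

#' Correct well scores against a DMSO-treated plate
#'
#' Removes well-position artifacts by converting each raw score against the
#' value of the vehicle-only (DMSO) plate at the same well position:
#' subtraction by default, division as a sensitivity-analysis mode.
#'
#' @param quant a `well_quant` table (the compound plate).
#' @param dmso_plate a `well_quant` table for the DMSO plate; must cover
#'   every well address present in `quant`.
#' @param config a [screen_config()].
#' @return `quant` with an added `score_converted` column.
#' @export
dmso_convert <- function(quant, dmso_plate, config = screen_config()) {
  idx <- match(quant$well, dmso_plate$well)
  if (anyNA(idx)) {
    stop_input("DMSO plate is missing well positions: ",
               paste(quant$well[is.na(idx)], collapse = ", "))
  }
  ref <- dmso_plate$score_raw[idx]
  if (config$dmso_correction_mode == "subtract") {
    quant$score_converted <- quant$score_raw - ref
  } else {
    bad <- abs(ref) < .Machine$double.eps^0.5
    if (any(bad)) {
      stop_degenerate("divide mode with zero DMSO score at wells: ",
                      paste(quant$well[bad], collapse = ", "))
    }
    quant$score_converted <- quant$score_raw / ref
  }
  quant
}

#' Robust Z-scores
#'
#' `Z_i = (x_i - median(x)) / (c * MAD(x))`, with the MAD taken as the median
#' absolute deviation from the sample median and `c` the Gaussian-consistency
#' constant (1.4826), i.e. the "robust standard deviation". The location and
#' scale are computed over all supplied values.
#'
#' @param converted numeric vector of converted scores (>= 3 values).
#' @param config a [screen_config()].
#' @return numeric vector of robust Z-scores.
#' @examples
#' robust_z(c(10, 12, 11, 9, 50))[5] # 39 / 1.4826 = 26.31
#' @export
robust_z <- function(converted, config = screen_config()) {
  x <- converted[!is.na(converted)]
  if (length(x) < 3) stop_input("robust Z needs at least 3 values")
  med <- median(x)
  raw_mad <- median(abs(x - med))
  if (raw_mad == 0) {
    stop_degenerate("degenerate scale: MAD of converted scores is zero")
  }
  (converted - med) / (config$robust_scale_constant * raw_mad)
}

#' Flag toxic wells by cell number
#'
#' A well is toxic when its cell count falls strictly below
#' `toxicity_fraction` (80%) of the reference cell number, the median count
#' of the DMSO control wells of the same run.
#'
#' @param quant a `well_quant` table.
#' @param dmso_reference_counts cell counts of the DMSO wells.
#' @param config a [screen_config()].
#' @return logical vector, one flag per row of `quant`.
#' @export
toxicity_filter <- function(quant, dmso_reference_counts,
                            config = screen_config()) {
  if (length(dmso_reference_counts) == 0) {
    stop_input("empty DMSO reference cell counts")
  }
  ref <- median(dmso_reference_counts)
  quant$cell_count < config$toxicity_fraction * ref
}

#' Call screening hits
#'
#' A compound is a hit when its robust Z strictly exceeds the threshold and
#' the well passed the toxicity gate. The hit list is ordered by descending
#' Z, ties broken by well address.
#'
#' @param screen a `screen_table` data.frame with `robust_z` and `toxic`.
#' @param config a [screen_config()].
#' @return `screen` with a `hit` column; attribute `"hits"` holds the sorted
#'   hit subset.
#' @export
call_hits <- function(screen, config = screen_config()) {
  if (!all(c("robust_z", "toxic") %in% names(screen))) {
    stop_input("screen table needs 'robust_z' and 'toxic' columns")
  }
  screen$hit <- !screen$toxic & !is.na(screen$robust_z) &
    screen$robust_z > config$hit_z_threshold
  hits <- screen[screen$hit, , drop = FALSE]
  hits <- hits[order(-hits$robust_z, hits$plate_id, hits$well), ,
               drop = FALSE]
  attr(screen, "hits") <- hits
  screen
}

#' Median fold change between treated and control scores
#'
#' @param treated_scores,control_scores numeric vectors.
#' @return `median(treated) / median(control)`; if the control median is not
#'   positive, `NA` with attribute `flag = "UNDEFINED_FOLD"` (no number is
#'   fabricated).
#' @export
fold_change <- function(treated_scores, control_scores) {
  if (!length(treated_scores) || !length(control_scores)) {
    stop_input("both score vectors must be non-empty")
  }
  mc <- median(control_scores)
  if (!is.finite(mc) || mc <= 0) {
    return(structure(NA_real_, flag = "UNDEFINED_FOLD"))
  }
  median(treated_scores) / mc
}

#' Score a full screen from quantified plates
#'
#' Composes the screening statistics: per-plate DMSO conversion, robust Z
#' over the pooled compound wells (or per plate), the toxicity gate against
#' the DMSO control wells of the compound plates, and hit calling.
#'
#' @param quants list of `well_quant` tables, one per compound plate.
#' @param dmso_quant `well_quant` table of the vehicle-only plate.
#' @param config a [screen_config()].
#' @return a `screen_table` data.frame (one row per compound well) with
#'   columns `plate_id,well,compound_id,score_raw,score_converted,robust_z,
#'   cell_count,cell_fraction,toxic,hit`; attributes `hits` and `summary`.
#' @export
score_screen <- function(quants, dmso_quant, config = screen_config()) {
  conv <- lapply(quants, dmso_convert, dmso_plate = dmso_quant,
                 config = config)
  all_q <- do.call(rbind, conv)
  dmso_counts <- all_q$cell_count[all_q$role == "dmso"]
  if (!length(dmso_counts)) dmso_counts <- dmso_quant$cell_count
  comp <- all_q[all_q$role == "compound", , drop = FALSE]
  comp$toxic <- toxicity_filter(comp, dmso_counts, config)
  comp$cell_fraction <- comp$cell_count / median(dmso_counts)
  if (config$pool_plates) {
    comp$robust_z <- robust_z(comp$score_converted, config)
  } else {
    comp$robust_z <- NA_real_
    for (p in unique(comp$plate_id)) {
      i <- comp$plate_id == p
      comp$robust_z[i] <- robust_z(comp$score_converted[i], config)
    }
  }
  comp <- call_hits(comp, config)
  out <- comp[, c("plate_id", "well", "compound_id", "score_raw",
                  "score_converted", "robust_z", "cell_count",
                  "cell_fraction", "toxic", "hit")]
  rownames(out) <- NULL
  attr(out, "hits") <- attr(comp, "hits")
  attr(out, "summary") <- list(
    n_wells = nrow(all_q) + nrow(dmso_quant), n_compound = nrow(out),
    n_dmso = length(dmso_counts), n_toxic = sum(out$toxic),
    n_hits = sum(out$hit), reference_cell_count = median(dmso_counts))
  class(out) <- c("screen_table", "data.frame")
  out
}
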