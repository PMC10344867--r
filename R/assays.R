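#' Insulin unit conversion
#'
#' Converts fasting plasma insulin from ng/ml to uIU/mL with the immunoassay
#' conversion factor 26.
#'
#' @param x insulin in ng/ml (vectorised, non-negative).
#' @return insulin in uIU/mL (`26 * x`).
#' @export
insulin_ng_to_uIU <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop_input("insulin must be non-negative")
  26 * x
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (uIU/mL) x glucose (mg/dL) / 405`.
#'
#' @param glucose fasting glucose, mg/dL (non-negative).
#' @param insulin fasting insulin, uIU/mL (non-negative).
#' @return HOMA-IR index (vectorised).
#' @examples
#' homa_ir(162, insulin_ng_to_uIU(0.5)) # 5.2
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(glucose < 0, na.rm = TRUE) || any(insulin < 0, na.rm = TRUE)) {
    stop_input("glucose and insulin must be non-negative")
  }
  insulin * glucose / 405
}

#' Fatty-acid oxidation activity from OD 492
#'
#' `FAO (IU/l) = 12.96 x (OD_reaction - OD_control)`. A negative net OD
#' (control above reaction) is non-physical and is clamped to 0 with a
#' `clamped` attribute flag for QC.
#'
#' @param od_reaction,od_control optical densities at 492 nm (vectorised,
#'   non-negative).
#' @return FAO activity in IU/l, with attribute `clamped` (logical vector).
#' @examples
#' fao_activity(0.5, 0.2) # 3.888
#' @export
fao_activity <- function(od_reaction, od_control) {
  if (any(od_reaction < 0, na.rm = TRUE) || any(od_control < 0, na.rm = TRUE)) {
    stop_input("optical densities must be non-negative")
  }
  net <- od_reaction - od_control
  clamped <- !is.na(net) & net < 0
  structure(12.96 * pmax(net, 0), clamped = clamped)
}

#' Batch assay conversions over a CSV
#'
#' Reads one row per sample, appends computed columns
#' (`insulin_uIU`, `homa_ir`, `fao_iu_l` where inputs are present) and
#' writes the result.
#'
#' @param path_in input CSV; recognised columns: `glucose_mg_dl`,
#'   `insulin_ng_ml` or `insulin_uIU`, `od_reaction`, `od_control`.
#' @param path_out output CSV.
#' @return the augmented data.frame, invisibly.
#' @export
convert_assay_csv <- function(path_in, path_out) {
  if (!file.exists(path_in)) stop_input("assay CSV not found: ", path_in)
  df <- read.csv(path_in, stringsAsFactors = FALSE)
  if ("insulin_ng_ml" %in% names(df) && !"insulin_uIU" %in% names(df)) {
    df$insulin_uIU <- insulin_ng_to_uIU(df$insulin_ng_ml)
  }
  if (all(c("glucose_mg_dl", "insulin_uIU") %in% names(df))) {
    df$homa_ir <- homa_ir(df$glucose_mg_dl, df$insulin_uIU)
  }
  if (all(c("od_reaction", "od_control") %in% names(df))) {
    fao <- fao_activity(df$od_reaction, df$od_control)
    df$fao_iu_l <- as.numeric(fao)
    df$fao_clamped <- attr(fao, "clamped")
  }
  write.csv(df, path_out, row.names = FALSE)
  invisible(df)
}
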