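#' Build a 384-well plate layout
#'
#' Assigns well roles for a screening plate. DMSO (vehicle) control wells are
#' spread across the plate by stratified sampling of the row-major well order
#' (one control per equal-sized block), so controls are never a contiguous
#' block and see the same positional field as compound wells. Compound wells
#' fill the remaining positions row-major; any leftover wells are `empty`.
#'
#' @param n_compounds number of compound wells.
#' @param n_dmso number of DMSO control wells.
#' @param seed integer seed controlling control-well placement.
#' @param n_rows,n_cols plate dimensions (default 16 x 24 = 384).
#' @param plate_id plate identifier stored with the layout.
#' @param compound_prefix prefix for generated compound identifiers.
#' @return a `plate_layout` data.frame with columns `plate_id`, `row`, `col`,
#'   `well`, `role` (one of compound/dmso/empty) and `compound_id` (non-NA
#'   exactly for compound wells).
#' @examples
#' lay <- make_plate_layout(352, 32, seed = 1)
#' table(lay$role)
#' @export
make_plate_layout <- function(n_compounds, n_dmso, seed,
                              n_rows = 16L, n_cols = 24L,
                              plate_id = "P01", compound_prefix = "CMPD") {
  n_wells <- n_rows * n_cols
  if (n_compounds < 0 || n_dmso < 0) {
    stop_input("well counts must be non-negative")
  }
  if (n_compounds + n_dmso > n_wells) {
    stop_input(sprintf(
      "capacity exceeded: %d compound + %d dmso wells > %d plate wells",
      n_compounds, n_dmso, n_wells))
  }
  idx <- seq_len(n_wells) # row-major order
  role <- rep("empty", n_wells)
  dmso_idx <- integer(0)
  if (n_dmso > 0) {
    # one control sampled per equal block of the traversal order
    breaks <- floor(seq(0, n_wells, length.out = n_dmso + 1))
    dmso_idx <- with_seed(seed, vapply(seq_len(n_dmso), function(k) {
      lo <- as.integer(breaks[k]) + 1L
      hi <- as.integer(breaks[k + 1L])
      if (hi < lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    }, integer(1)))
    role[dmso_idx] <- "dmso"
  }
  free <- setdiff(idx, dmso_idx)
  comp_idx <- free[seq_len(n_compounds)]
  role[comp_idx] <- "compound"

  row <- ((idx - 1L) %/% n_cols) + 1L
  col <- ((idx - 1L) %% n_cols) + 1L
  compound_id <- rep(NA_character_, n_wells)
  compound_id[comp_idx] <- sprintf("%s%04d", compound_prefix,
                                   seq_len(n_compounds))
  out <- data.frame(
    plate_id = plate_id, row = row, col = col,
    well = well_name(row, col), role = role,
    compound_id = compound_id, stringsAsFactors = FALSE)
  attr(out, "n_rows") <- as.integer(n_rows)
  attr(out, "n_cols") <- as.integer(n_cols)
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Write / read a plate map CSV
#'
#' Plate maps are exchanged as CSV with columns
#' `plate_id,row,col,role,compound_id`, rows as letters (A-P) and columns as
#' integers (1-24).
#'
#' @param layout a `plate_layout`.
#' @param path file path.
#' @return `read_plate_map` returns a `plate_layout`.
#' @export
write_plate_map <- function(layout, path) {
  df <- data.frame(plate_id = layout$plate_id,
                   row = LETTERS[layout$row], col = layout$col,
                   role = layout$role, compound_id = layout$compound_id,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop_input("plate map not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("plate_id", "row", "col", "role", "compound_id")
  if (!all(need %in% names(df))) {
    stop_input("plate map must have columns ", paste(need, collapse = ","))
  }
  row <- match(df$row, LETTERS)
  out <- data.frame(plate_id = df$plate_id, row = row, col = df$col,
                    well = well_name(row, df$col), role = df$role,
                    compound_id = df$compound_id, stringsAsFactors = FALSE)
  attr(out, "n_rows") <- max(out$row)
  attr(out, "n_cols") <- max(out$col)
  class(out) <- c("plate_layout", "data.frame")
  out
}
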