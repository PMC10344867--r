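#' Simulate ground truth for a screening plate
#'
#' Draws a per-well ground truth table for every non-empty well of a layout:
#' seeded cell count, lipid-droplet density, the fraction of droplet GFP lost
#' to lipophagy (`quench_fraction`) and a viability multiplier
#' (`toxicity_factor`). A chosen number of compound wells are spiked as
#' lipophagy actives (quench_fraction = `active_quench`) and, disjointly, as
#' toxic (`toxicity_factor = toxic_factor`). DMSO wells are never spiked.
#'
#' Cell numbers model a dispenser seeding a fixed target with small
#' plate-to-well variation (truncated normal, CV `cell_cv`), not Poisson
#' colonisation: automated dispensers deliver cell suspensions with a few
#' percent well-to-well CV.
#'
#' @param layout a `plate_layout`.
#' @param n_actives number of compound wells spiked as lipophagy actives.
#' @param active_quench quench fraction given to active wells, in (0, 1].
#' @param n_toxic number of compound wells spiked as toxic.
#' @param seed integer seed.
#' @param mean_cells expected seeded cells per well.
#' @param cell_cv well-to-well CV of the seeded cell count.
#' @param droplet_density expected lipid droplets per cell.
#' @param toxic_factor viability multiplier for toxic wells, in (0, 1).
#' @return data.frame (`screen_truth`) with one row per non-empty well:
#'   `plate_id,row,col,well,role,compound_id,true_cell_count,quench_fraction,
#'   toxicity_factor,droplet_density`.
#' @examples
#' lay <- make_plate_layout(100, 20, seed = 1)
#' tr <- simulate_screen_truth(lay, n_actives = 5, active_quench = 0.9,
#'                             n_toxic = 0, seed = 7)
#' sum(tr$quench_fraction > 0)
#' @export
simulate_screen_truth <- function(layout, n_actives, active_quench, n_toxic,
                                  seed, mean_cells = 120, cell_cv = 0.05,
                                  droplet_density = 3, toxic_factor = 0.5) {
  stopifnot(inherits(layout, "plate_layout"))
  if (n_actives > 0 && (active_quench <= 0 || active_quench > 1)) {
    stop_input("'active_quench' must be in (0, 1]")
  }
  wells <- layout[layout$role != "empty", , drop = FALSE]
  comp <- which(wells$role == "compound")
  if (n_actives + n_toxic > length(comp)) {
    stop_input(sprintf(
      "%d actives + %d toxic exceed %d compound wells",
      n_actives, n_toxic, length(comp)))
  }
  n <- nrow(wells)
  out <- with_seed(seed, {
    cells <- pmax(0L, as.integer(round(rnorm(n, mean_cells,
                                             cell_cv * mean_cells))))
    spiked <- if (n_actives + n_toxic > 0) {
      sample(comp, n_actives + n_toxic)
    } else integer(0)
    quench <- rep(0, n)
    quench[spiked[seq_len(n_actives)]] <- active_quench
    tox <- rep(1, n)
    if (n_toxic > 0) tox[spiked[n_actives + seq_len(n_toxic)]] <- toxic_factor
    data.frame(wells[, c("plate_id", "row", "col", "well", "role",
                         "compound_id")],
               true_cell_count = cells, quench_fraction = quench,
               toxicity_factor = tox, droplet_density = droplet_density,
               stringsAsFactors = FALSE)
  })
  rownames(out) <- NULL
  attr(out, "n_rows") <- attr(layout, "n_rows")
  attr(out, "n_cols") <- attr(layout, "n_cols")
  class(out) <- c("screen_truth", "data.frame")
  out
}
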