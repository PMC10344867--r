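#' Simulate complete screening inputs (plates, truth, images)
#'
#' Builds the whole input side of a screen: compound plates (each with
#' in-plate DMSO control wells), a vehicle-only DMSO plate for position
#' correction, per-well ground truth with spiked actives and toxic wells,
#' and rendered 3-channel images. Actives and toxic wells are drawn over the
#' pooled compound wells of all plates.
#'
#' @param n_compounds total compound wells across plates.
#' @param n_actives,n_toxic spiked active / toxic compound wells.
#' @param active_quench quench fraction of the actives.
#' @param seed integer master seed.
#' @param params an [imaging_params()]; each plate derives its own
#'   imaging substream from `seed`.
#' @param compounds_per_plate,n_dmso_per_plate plate composition (default
#'   352 + 32 = 384).
#' @param mean_cells,cell_cv,droplet_density,toxic_factor forwarded to
#'   [simulate_screen_truth()].
#' @param render render images (set FALSE to get layouts/truth only).
#' @return list with `plates` (each: `layout`, `truth`, `images`),
#'   `dmso_plate` (same fields), and `truth_all` (row-bound truth of the
#'   compound plates).
#' @export
simulate_screen_inputs <- function(n_compounds, n_actives = 0,
                                   n_toxic = 0, active_quench = 0.9, seed = 1L,
                                   params = imaging_params(),
                                   compounds_per_plate = 352L,
                                   n_dmso_per_plate = 32L,
                                   mean_cells = 120, cell_cv = 0.05,
                                   droplet_density = 3, toxic_factor = 0.5,
                                   render = TRUE) {
  n_plates <- ceiling(n_compounds / compounds_per_plate)
  counts <- rep(compounds_per_plate, n_plates)
  if (n_plates > 0) {
    counts[n_plates] <- n_compounds - compounds_per_plate * (n_plates - 1)
  }
  plates <- lapply(seq_len(n_plates), function(p) {
    lay <- make_plate_layout(counts[p], n_dmso_per_plate,
                             seed = derive_seed(seed, p),
                             plate_id = sprintf("P%02d", p),
                             compound_prefix = sprintf("C%02d_", p))
    truth <- simulate_screen_truth(lay, 0, 1, 0,
                                   seed = derive_seed(seed, 100 + p),
                                   mean_cells = mean_cells, cell_cv = cell_cv,
                                   droplet_density = droplet_density)
    list(layout = lay, truth = truth)
  })
  # global spike-in assignment over pooled compound wells
  if (n_actives + n_toxic > 0) {
    comp_index <- do.call(rbind, lapply(seq_along(plates), function(p) {
      w <- which(plates[[p]]$truth$role == "compound")
      data.frame(plate = p, row = w)
    }))
    if (n_actives + n_toxic > nrow(comp_index)) {
      stop_input("more spike-ins than compound wells")
    }
    pick <- with_seed(derive_seed(seed, 999),
                      sample(nrow(comp_index), n_actives + n_toxic))
    act <- comp_index[pick[seq_len(n_actives)], , drop = FALSE]
    tox <- comp_index[pick[n_actives + seq_len(n_toxic)], , drop = FALSE]
    for (k in seq_len(nrow(act))) {
      plates[[act$plate[k]]]$truth$quench_fraction[act$row[k]] <- active_quench
    }
    for (k in seq_len(nrow(tox))) {
      plates[[tox$plate[k]]]$truth$toxicity_factor[tox$row[k]] <- toxic_factor
    }
  }
  dmso_lay <- make_plate_layout(0, 384, seed = derive_seed(seed, 998),
                                plate_id = "DMSO")
  dmso_truth <- simulate_screen_truth(dmso_lay, 0, 1, 0,
                                      seed = derive_seed(seed, 997),
                                      mean_cells = mean_cells,
                                      cell_cv = cell_cv,
                                      droplet_density = droplet_density)
  if (render) {
    for (p in seq_along(plates)) {
      pp <- params
      pp$rng_seed <- derive_seed(seed, 500 + p)
      plates[[p]]$images <- render_plate_images(plates[[p]]$truth, pp)
    }
    pp <- params
    pp$rng_seed <- derive_seed(seed, 996)
    dmso_images <- render_plate_images(dmso_truth, pp)
  } else {
    dmso_images <- NULL
  }
  list(plates = plates,
       dmso_plate = list(layout = dmso_lay, truth = dmso_truth,
                         images = dmso_images),
       truth_all = do.call(rbind, lapply(plates, `[[`, "truth")))
}

#' Simulate, render and quantify a screen without keeping images
#'
#' Memory-lean variant of [simulate_screen_inputs()] + [quantify_plate()]
#' for large screens: each well is rendered and quantified immediately and
#' its raster discarded, so a full ~3500-compound screen at 256 x 256 px
#' fits in a few hundred megabytes instead of several gigabytes.
#'
#' @inheritParams simulate_screen_inputs
#' @param seg a [segmentation_params()].
#' @return list with `quants` (list of `well_quant`, one per compound
#'   plate), `dmso_quant`, and `truth_all`.
#' @export
simulate_quantified_screen <- function(n_compounds, n_actives = 0,
                                       n_toxic = 0, active_quench = 0.9,
                                       seed = 1L,
                                       params = imaging_params(),
                                       seg = segmentation_params(),
                                       compounds_per_plate = 352L,
                                       n_dmso_per_plate = 32L,
                                       mean_cells = 120, cell_cv = 0.05,
                                       droplet_density = 3,
                                       toxic_factor = 0.5) {
  sim <- simulate_screen_inputs(
    n_compounds = n_compounds, n_actives = n_actives, n_toxic = n_toxic,
    active_quench = active_quench, seed = seed, params = params,
    compounds_per_plate = compounds_per_plate,
    n_dmso_per_plate = n_dmso_per_plate, mean_cells = mean_cells,
    cell_cv = cell_cv, droplet_density = droplet_density,
    toxic_factor = toxic_factor, render = FALSE)
  stream_quant <- function(truth, layout, plate_seed) {
    pp <- params
    pp$rng_seed <- plate_seed
    dims <- c(attr(truth, "n_rows") %||% 16L, attr(truth, "n_cols") %||% 24L)
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      img <- render_well_image(truth[i, ], pp, plate_dims = dims)
      quantify_one_well(img, seg)
    })
    out <- cbind(truth[, c("plate_id", "row", "col", "well", "role",
                           "compound_id")], do.call(rbind, rows))
    rownames(out) <- NULL
    class(out) <- c("well_quant", "data.frame")
    out
  }
  quants <- lapply(seq_along(sim$plates), function(p) {
    stream_quant(sim$plates[[p]]$truth, sim$plates[[p]]$layout,
                 derive_seed(seed, 500 + p))
  })
  dmso_quant <- stream_quant(sim$dmso_plate$truth, sim$dmso_plate$layout,
                             derive_seed(seed, 996))
  list(quants = quants, dmso_quant = dmso_quant, truth_all = sim$truth_all)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_input("config must be a list or a JSON path")
  config
}

#' Run the image-based screening pipeline
#'
#' Quantifies every plate, converts scores against the DMSO plate, computes
#' robust Z over the pooled compound wells, applies the toxicity gate and
#' calls hits; writes a screen results TSV and a JSON run summary stamped
#' with the seed and a config hash.
#'
#' The config (list or JSON path) either points at existing inputs
#' (`plate_maps`: plate-map CSVs, `image_dir`: well TIFFs,
#' `dmso_plate_map`) or requests simulation via a `simulate` block
#' (fields of [simulate_screen_inputs()]). Optional blocks `segmentation`
#' and `screen` override [segmentation_params()] / [screen_config()]
#' defaults; `output_dir` enables file output.
#'
#' @param config list or path to a JSON config.
#' @return the `screen_table`, with attributes `hits` and `summary`.
#' @export
run_screen <- function(config) {
  config <- read_run_config(config)
  seg <- do.call(segmentation_params,
                 as.list(config[["segmentation"]] %||% list()))
  scfg <- do.call(screen_config, as.list(config[["screen"]] %||% list()))
  if (!is.null(config[["simulate"]])) {
    sim <- do.call(simulate_screen_inputs, as.list(config[["simulate"]]))
    plates <- sim$plates
    dmso <- sim$dmso_plate
    quants <- lapply(plates, function(p) {
      quantify_plate(p$images, p$layout, seg)
    })
    dmso_quant <- quantify_plate(dmso$images, dmso$layout, seg)
  } else {
    if (is.null(config[["plate_maps"]]) || is.null(config[["image_dir"]]) ||
        is.null(config[["dmso_plate_map"]])) {
      stop_input("config needs plate_maps, image_dir and dmso_plate_map ",
                 "(or a 'simulate' block)")
    }
    missing_maps <- config[["plate_maps"]][!file.exists(config[["plate_maps"]])]
    if (length(missing_maps) || !file.exists(config[["dmso_plate_map"]])) {
      stop_input("missing input files: ",
                 paste(c(missing_maps,
                         config[["dmso_plate_map"]][
                           !file.exists(config[["dmso_plate_map"]])]),
                       collapse = ", "))
    }
    quants <- lapply(config[["plate_maps"]], function(pm) {
      quantify_plate(config[["image_dir"]], read_plate_map(pm), seg)
    })
    dmso_quant <- quantify_plate(config[["image_dir"]],
                                 read_plate_map(config[["dmso_plate_map"]]), seg)
  }
  screen <- score_screen(quants, dmso_quant, scfg)
  summary <- attr(screen, "summary")
  summary$seed <- config[["simulate"]]$seed %||% NA
  summary$config_hash <- config_hash(config)
  summary$config <- config[setdiff(names(config), "simulate")]
  summary$warnings <- list(
    empty_mask_wells = sum(grepl("EMPTY_MASK",
                                 unlist(lapply(quants, `[[`, "flags")))),
    no_cells_wells = sum(grepl("NO_CELLS",
                               unlist(lapply(quants, `[[`, "flags")))))
  attr(screen, "summary") <- summary
  if (!is.null(config[["output_dir"]])) {
    dir.create(config[["output_dir"]], showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(config[["output_dir"]], "screen_results.tsv")
    write.table(as.data.frame(screen), tsv, sep = "\t", row.names = FALSE,
                quote = FALSE)
    jsonlite::write_json(summary,
                         file.path(config[["output_dir"]], "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  screen
}

#' Run the nested case-control pipeline
#'
#' Filters the registry (missing data, NYHA II-IV heart failure, age outside
#' 20-80), matches exposed to unexposed subjects 1:1 on sex/AF (exact) and
#' age/BMI (calipers), and reports prevalence per group, the unstratified
#' chi-square, the Mantel-Haenszel test over sex x AF strata, and covariate
#' balance, as a JSON-able list.
#'
#' Config fields: `registry_csv` (or `registry`, an in-memory data.frame),
#' optional `matching` (fields of [matching_criteria()]), `seed`,
#' `output_dir`.
#'
#' @param config list or path to a JSON config.
#' @return list with `filter_report`, `matching`, `prevalence`, `counts`,
#'   `chi_square`, `mantel_haenszel`, `balance`.
#' @export
run_casecontrol <- function(config) {
  config <- read_run_config(config)
  registry <- if (!is.null(config[["registry"]])) {
    config[["registry"]]
  } else {
    if (is.null(config[["registry_csv"]])) {
      stop_input("config needs 'registry_csv' or 'registry'")
    }
    read_registry_csv(config[["registry_csv"]])
  }
  crit <- do.call(matching_criteria, as.list(config[["matching"]] %||% list()))
  filt <- apply_cohort_filters(registry)
  if (filt$report$n_exposed_remaining == 0) {
    stop_input("no exposed (digoxin) subjects remain after filtering")
  }
  matched <- match_case_control(filt$registry, crit,
                                seed = config[["seed"]] %||% 1L)
  tab <- build_contingency(matched$cohort)
  strata <- stratified_tables(matched$cohort)
  mh <- mantel_haenszel(strata)
  bal <- covariate_balance(matched$cohort, "matched_group", c("age", "bmi"))
  res <- list(
    filter_report = unclass(filt$report),
    matching = list(n_pairs = nrow(matched$pairs),
                    n_unmatched_cases = length(matched$unmatched_cases),
                    criteria = unclass(crit)),
    counts = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
    prevalence = as.list(prevalence(tab)),
    chi_square = chi_square_2x2(tab),
    mantel_haenszel = mh,
    balance = bal,
    seed = config[["seed"]] %||% 1L,
    config_hash = config_hash(config))
  if (!is.null(config[["output_dir"]])) {
    dir.create(config[["output_dir"]], showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, file.path(config[["output_dir"]],
                                        "casecontrol_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    pairs_csv <- file.path(config[["output_dir"]], "matched_pairs.csv")
    write.csv(matched$pairs, pairs_csv, row.names = FALSE)
  }
  attr(res, "matched") <- matched
  res
}
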