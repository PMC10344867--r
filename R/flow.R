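#' Simulate a flow-cytometry-like event table
#'
#' Draws events from a mixture of per-channel log-normal components
#' (intensities are strictly positive, as on a cytometer). Component counts
#' are multinomial with the supplied weights; the generating component of
#' each event is kept as ground truth.
#'
#' @param mixture list of components, each a list with `weight` and
#'   `channels`, the latter a named list of `c(meanlog, sdlog)` per channel.
#'   All components must declare the same channels.
#' @param n_events number of events (>= 1).
#' @param seed integer seed.
#' @param sample_label optional label stored with the table.
#' @return a `flow_events` data.frame (one row per event, one column per
#'   channel) with attributes `component` (integer ground-truth labels) and
#'   `sample_label`.
#' @examples
#' mix <- list(
#'   list(weight = 0.3, channels = list(GFP = c(3, 0.3), mCherry = c(6, 0.3))),
#'   list(weight = 0.7, channels = list(GFP = c(6, 0.3), mCherry = c(6, 0.3))))
#' ev <- simulate_flow_events(mix, 1000, seed = 2)
#' @export
simulate_flow_events <- function(mixture, n_events, seed,
                                 sample_label = "sample") {
  if (!length(mixture)) stop_input("empty mixture")
  if (n_events < 1) stop_input("n_events must be >= 1")
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop_input("mixture weights must be non-negative and sum to 1")
  }
  chans <- names(mixture[[1]]$channels)
  if (!length(chans)) stop_input("components must declare >= 1 channel")
  for (m in mixture) {
    if (!identical(sort(names(m$channels)), sort(chans))) {
      stop_input("all mixture components must share the same channels")
    }
  }
  with_seed(seed, {
    comp <- sample.int(length(mixture), n_events, replace = TRUE, prob = w)
    out <- as.data.frame(lapply(setNames(chans, chans), function(ch) {
      mu <- vapply(mixture, function(m) m$channels[[ch]][1], numeric(1))
      sg <- vapply(mixture, function(m) m$channels[[ch]][2], numeric(1))
      rlnorm(n_events, mu[comp], sg[comp])
    }))
    attr(out, "component") <- comp
    attr(out, "sample_label") <- sample_label
    class(out) <- c("flow_events", "data.frame")
    out
  })
}

#' Gate specification
#'
#' A conjunction of per-channel predicates, each keeping events `"above"`
#' (`>=`) or `"below"` (`<`) a threshold, on raw or `log10(x + 1)` scale.
#'
#' @param ... one or more predicates built with [gate_above()] /
#'   [gate_below()].
#' @return a `gate_spec` list.
#' @export
gate_spec <- function(...) {
  preds <- list(...)
  if (!length(preds)) stop_input("a gate needs at least one predicate")
  structure(preds, class = "gate_spec")
}

#' @rdname gate_spec
#' @param channel channel name.
#' @param threshold finite threshold.
#' @param transform `"raw"` or `"log10"` (log10(x + 1)).
#' @export
gate_above <- function(channel, threshold, transform = c("raw", "log10")) {
  if (!is.finite(threshold)) stop_input("gate threshold must be finite")
  list(channel = channel, op = "above", threshold = threshold,
       transform = match.arg(transform))
}

#' @rdname gate_spec
#' @export
gate_below <- function(channel, threshold, transform = c("raw", "log10")) {
  if (!is.finite(threshold)) stop_input("gate threshold must be finite")
  list(channel = channel, op = "below", threshold = threshold,
       transform = match.arg(transform))
}

#' Fraction of events inside a gate
#'
#' @param events a `flow_events` table (>= 1 event).
#' @param gate a [gate_spec()].
#' @return fraction in \[0, 1\] of events satisfying every predicate.
#' @export
gate_fraction <- function(events, gate) {
  if (!NROW(events)) stop_input("empty event table")
  keep <- rep(TRUE, NROW(events))
  for (p in gate) {
    if (!p$channel %in% names(events)) {
      stop_input("unknown channel in gate: ", p$channel)
    }
    x <- events[[p$channel]]
    if (p$transform == "log10") x <- log10(x + 1)
    keep <- keep & if (p$op == "above") x >= p$threshold else x < p$threshold
  }
  mean(keep)
}

#' Lipophagy-positive fraction from the tandem reporter
#'
#' Events whose lipid-droplet GFP has been quenched (below `gfp_cut`) while
#' the acid-stable mCherry is retained (at or above `mcherry_cut`).
#' mCherry-negative debris is never counted, whatever its GFP.
#'
#' @param events a `flow_events` table with GFP and mCherry channels.
#' @param gfp_cut,mcherry_cut gate thresholds on raw intensity.
#' @return fraction in \[0, 1\].
#' @export
lipophagy_positive_fraction <- function(events, gfp_cut, mcherry_cut) {
  gate_fraction(events, gate_spec(gate_below("GFP", gfp_cut),
                                  gate_above("mCherry", mcherry_cut)))
}

#' Surface-marker positive fraction against a negative control
#'
#' Sets the positivity threshold at the stated percentile of the negative
#' control's channel distribution and returns the fraction of sample events
#' strictly above it (so a sample distributed like the control yields
#' approximately `1 - percentile/100`).
#'
#' @param events sample `flow_events`.
#' @param negative_control control `flow_events` (e.g. a knockout line).
#' @param channel channel name present in both tables.
#' @param percentile control percentile defining the threshold (default 99).
#' @return fraction in \[0, 1\].
#' @export
surface_positive_fraction <- function(events, negative_control, channel,
                                      percentile = 99) {
  if (!NROW(events) || !NROW(negative_control)) {
    stop_input("empty event table")
  }
  if (!channel %in% names(events) || !channel %in% names(negative_control)) {
    stop_input("channel '", channel, "' missing from events or control")
  }
  thr <- quantile(negative_control[[channel]], percentile / 100, names = FALSE)
  mean(events[[channel]] > thr)
}

#' Write / read flow events as CSV
#' @param events a `flow_events` table.
#' @param path file path.
#' @export
write_flow_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  if (!file.exists(path)) stop_input("flow CSV not found: ", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("flow_events", "data.frame")
  out
}
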