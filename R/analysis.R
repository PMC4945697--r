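# Post-processing of network solutions: per-lumen flow splits at matched
# axial stations, mass-conservation audit, and the tear-count sensitivity
# experiment.

#' True/false lumen flow split at a matched station
#'
#' Cycle-mean flow through the true-lumen and false-lumen elements at one
#' axial station of the dissection, with the per-lumen fractions of the
#' total. The station must pair a true-lumen and a false-lumen element at
#' the same axial position, as recorded in the topology's station table.
#'
#' @param sol a `network_solution` from [simulate_network()].
#' @param level station identifier: an integer/station name matched against
#'   the topology's `stations` table, or a list `list(tl=, fl=)` of element
#'   names.
#' @return List with `Q_TL`, `Q_FL`, `total` (mm^3/s, cycle means),
#'   `fraction_TL`, `fraction_FL` (percent, summing to 100).
#' @export
lumen_flow_split <- function(sol, level) {
  stopifnot(inherits(sol, "network_solution"))
  if (is.list(level)) {
    tl_el <- level$tl
    fl_el <- level$fl
  } else {
    st <- sol$topology$stations
    if (is.null(st))
      stop("this topology has no matched true/false lumen stations")
    row <- st[st$station == level, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("unknown station: ", level)
    tl_el <- row$tl_element
    fl_el <- row$fl_element
  }
  i_tl <- match(tl_el, sol$elements$name)
  i_fl <- match(fl_el, sol$elements$name)
  if (is.na(i_tl) || is.na(i_fl))
    stop("station elements not found in solution: ", tl_el, " / ", fl_el)
  q_tl <- mean(sol$flows[, i_tl])
  q_fl <- mean(sol$flows[, i_fl])
  tot <- q_tl + q_fl
  list(Q_TL = q_tl, Q_FL = q_fl, total = tot,
       fraction_TL = 100 * q_tl / tot,
       fraction_FL = 100 * q_fl / tot)
}

#' Global mass-conservation audit of a converged solution
#'
#' In a rigid, incompressible 0D network the cycle-mean inflow must equal
#' the summed cycle-mean outlet flows.
#'
#' @param sol a `network_solution`.
#' @return List with `inflow`, `outflow` (mm^3/s) and `rel_error`.
#' @export
mass_conservation <- function(sol) {
  q_in <- mean(sol$inflow)
  q_out <- sum(sol$outlet_summary$mean_flow)
  list(inflow = q_in, outflow = q_out,
       rel_error = abs(q_out - q_in) / abs(q_in))
}

#' Maximum trans-septal pressure difference per station
#'
#' For each matched station, the maximum over the cycle of the absolute
#' pressure difference between the true-lumen and false-lumen nodes.
#' Connecting tears let the lumina equalise, so adding tears should weakly
#' decrease these values.
#'
#' @param sol a `network_solution` whose topology carries stations.
#' @return Named numeric vector (canonical pressure units), one value per
#'   station.
#' @export
septal_pressure_gap <- function(sol) {
  st <- sol$topology$stations
  if (is.null(st)) stop("topology has no stations")
  out <- vapply(seq_len(nrow(st)), function(k) {
    i_tl <- match(st$tl_node[k], sol$nodes)
    i_fl <- match(st$fl_node[k], sol$nodes)
    max(abs(sol$pressures[, i_tl] - sol$pressures[, i_fl]))
  }, numeric(1))
  stats::setNames(out, st$station)
}

#' Tear-count sensitivity experiment
#'
#' Simulates a base configuration and a set of variants sharing the same
#' station naming, and tabulates the percent change (relative to base) of
#' mean and peak true/false-lumen flow and peak lumen pressure at a probe
#' station. The probe defaults to the most distal thoracic station, just
#' proximal to the visceral branches.
#'
#' @param base_config base network configuration list.
#' @param variants named list of variant configuration lists.
#' @param inlet inflow [waveform()] shared by all runs.
#' @param probe station identifier (default 3).
#' @param ... further arguments to [simulate_network()].
#' @return Data frame, one row per variant, with base-relative percent
#'   changes `d_mean_TL`, `d_peak_TL`, `d_mean_FL`, `d_peak_FL`,
#'   `d_peak_P_TL`, plus the raw base row.
#' @export
tear_sensitivity_study <- function(base_config, variants, inlet, probe = 3,
                                   ...) {
  probe_metrics <- function(cfg) {
    sol <- simulate_network(build_network(cfg), inlet, ...)
    st <- sol$topology$stations
    row <- st[st$station == probe, , drop = FALSE]
    if (nrow(row) != 1L) stop("probe station not found: ", probe)
    i_tl <- match(row$tl_element, sol$elements$name)
    i_fl <- match(row$fl_element, sol$elements$name)
    n_tl <- match(row$tl_node, sol$nodes)
    list(mean_TL = mean(sol$flows[, i_tl]),
         peak_TL = max(sol$flows[, i_tl]),
         mean_FL = mean(sol$flows[, i_fl]),
         peak_FL = max(sol$flows[, i_fl]),
         peak_P_TL = max(sol$pressures[, n_tl]))
  }
  base <- probe_metrics(base_config)
  pct <- function(v, b) 100 * (v - b) / b
  rows <- lapply(names(variants), function(nm) {
    m <- probe_metrics(variants[[nm]])
    data.frame(variant = nm,
               d_mean_TL = pct(m$mean_TL, base$mean_TL),
               d_peak_TL = pct(m$peak_TL, base$peak_TL),
               d_mean_FL = pct(m$mean_FL, base$mean_FL),
               d_peak_FL = pct(m$peak_FL, base$peak_FL),
               d_peak_P_TL = pct(m$peak_P_TL, base$peak_P_TL),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "base") <- as.data.frame(base)
  res
}
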