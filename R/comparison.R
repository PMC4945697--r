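# Measurement-versus-simulation comparison arithmetic: signed relative
# errors per station and lumen, three-station averages, and per-lumen
# fractions of total descending flow.

#' Signed relative error of a simulated value against a measurement
#'
#' `100 * (sim - meas) / meas`, in percent.
#'
#' @param sim simulated value.
#' @param meas measured (reference) value; must be non-zero.
#' @return Signed percent error.
#' @examples
#' relative_error(51.4, 55.6)  # -7.55...
#' relative_error(12.7, 7.9)   # +60.76...
#' @export
relative_error <- function(sim, meas) {
  if (any(meas == 0)) stop("relative_error undefined for zero measurement")
  100 * (sim - meas) / meas
}

#' Per-lumen fraction of total flow across stations
#'
#' Ratio-of-means convention: `100 * mean(lumen) / mean(total)` over the
#' supplied stations. The mean-of-ratios variant is also returned, along
#' with the display value rounded to the nearest integer.
#'
#' @param lumen_means per-station lumen mean flows.
#' @param total_means per-station total mean flows (same length).
#' @return List with `fraction` (ratio of means, percent), `fraction_mor`
#'   (mean of per-station ratios), and `display` (integer-rounded
#'   ratio-of-means).
#' @examples
#' lumen_fraction(c(40.6, 42.5, 42.4), c(55.6, 53.8, 50.3))$display  # 79
#' @export
lumen_fraction <- function(lumen_means, total_means) {
  if (length(lumen_means) != length(total_means))
    stop("lumen and total vectors differ in length")
  fr <- 100 * mean(lumen_means) / mean(total_means)
  list(fraction = fr,
       fraction_mor = mean(100 * lumen_means / total_means),
       display = round(fr))
}

#' Load the packaged per-lumen PC-MRI measurement set
#'
#' Cycle-mean true-lumen, false-lumen and total flows at the proximal,
#' medial and distal stations of the descending thoracic aorta, in mm^3/s.
#'
#' @param path optional CSV with columns `location,lumen,mean_flow_mm3_s`.
#' @return Data frame in wide form: `location`, `Q_TL`, `Q_FL`, `Q_total`.
#' @export
load_lumen_measurements <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pcmri_measurements.csv",
                        package = "aorta0d", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  wide <- data.frame(location = unique(df$location), stringsAsFactors = FALSE)
  pick <- function(lum) df$mean_flow_mm3_s[match(
    paste(wide$location, lum), paste(df$location, df$lumen))]
  wide$Q_TL <- pick("true")
  wide$Q_FL <- pick("false")
  wide$Q_total <- pick("total")
  if (anyNA(wide$Q_total)) wide$Q_total <- wide$Q_TL + wide$Q_FL
  bad <- abs(wide$Q_total - (wide$Q_TL + wide$Q_FL)) > 0.01 * wide$Q_total
  if (any(bad))
    stop("inconsistent measurement set at location ", wide$location[bad][1L],
         ": total differs from TL + FL by more than 1%")
  wide
}

#' Build a measurement-versus-simulation comparison report
#'
#' Pairs simulated per-lumen mean flows with measurements at each station,
#' computes signed relative errors and their three-station averages, and
#' the per-lumen fractions of total flow for both data sets.
#'
#' Simulated input may be a `network_solution` (station means are extracted
#' through [lumen_flow_split()] using `station_map`) or a data frame with
#' columns `location`, `Q_TL`, `Q_FL` (and optionally `Q_total`; defaults
#' to their sum).
#'
#' @param sim simulated values (see Details).
#' @param measurements measurement data frame as returned by
#'   [load_lumen_measurements()].
#' @param station_map named vector mapping measurement locations to
#'   topology stations, e.g. `c(proximal = 1, medial = 2, distal = 3)`.
#'   Only used when `sim` is a `network_solution`.
#' @return Object of class `comparison_report`: `table` (per location and
#'   lumen: simulated, measured, relative error), `avg_errors` (named
#'   three-station mean errors), `fractions` (measured and simulated
#'   TL/FL fractions).
#' @export
build_comparison_report <- function(sim, measurements,
                                    station_map = c(proximal = 1,
                                                    medial = 2,
                                                    distal = 3)) {
  if (inherits(sim, "network_solution")) {
    missing_loc <- setdiff(measurements$location, names(station_map))
    if (length(missing_loc))
      stop("no station mapped for location: ", missing_loc[1L])
    sim <- do.call(rbind, lapply(measurements$location, function(loc) {
      sp <- lumen_flow_split(sim, station_map[[loc]])
      data.frame(location = loc, Q_TL = sp$Q_TL, Q_FL = sp$Q_FL,
                 Q_total = sp$total, stringsAsFactors = FALSE)
    }))
  }
  sim <- as.data.frame(sim)
  if (is.null(sim$Q_total)) sim$Q_total <- sim$Q_TL + sim$Q_FL
  if (!all(measurements$location %in% sim$location))
    stop("simulated values missing for location: ",
         setdiff(measurements$location, sim$location)[1L])
  i <- match(measurements$location, sim$location)
  lumens <- c(total = "Q_total", false = "Q_FL", true = "Q_TL")
  tab <- do.call(rbind, lapply(names(lumens), function(lu) {
    col <- lumens[[lu]]
    data.frame(location = measurements$location,
               lumen = lu,
               simulated = sim[[col]][i],
               measured = measurements[[col]],
               rel_error = relative_error(sim[[col]][i],
                                          measurements[[col]]),
               stringsAsFactors = FALSE)
  }))
  avg <- vapply(names(lumens), function(lu)
    mean(tab$rel_error[tab$lumen == lu]), numeric(1))
  fr <- list(
    measured_FL = lumen_fraction(measurements$Q_FL, measurements$Q_total),
    measured_TL = lumen_fraction(measurements$Q_TL, measurements$Q_total),
    simulated_FL = lumen_fraction(sim$Q_FL[i], sim$Q_total[i]),
    simulated_TL = lumen_fraction(sim$Q_TL[i], sim$Q_total[i]))
  structure(list(table = tab, avg_errors = avg, fractions = fr),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 1, ...) {
  tab <- x$table
  tab$simulated <- round(tab$simulated, digits)
  tab$measured <- round(tab$measured, digits)
  tab$rel_error <- round(tab$rel_error, digits)
  print(tab, row.names = FALSE)
  cat("\nAverage errors over locations (%):\n")
  print(round(x$avg_errors, digits))
  cat(sprintf("\nLumen fractions: measured FL %d%% / TL %d%%, simulated FL %d%% / TL %d%%\n",
              x$fractions$measured_FL$display, x$fractions$measured_TL$display,
              x$fractions$simulated_FL$display, x$fractions$simulated_TL$display))
  invisible(x)
}

#' Write a comparison report table to CSV
#'
#' Deterministic serialisation: identical inputs give byte-identical files.
#'
#' @param report a `comparison_report`.
#' @param path output file path.
#' @export
write_comparison_csv <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  utils::write.csv(format(report$table, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
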