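# Periodic waveform container. A waveform is one period of a uniformly or
# non-uniformly sampled periodic signal: strictly increasing sample times
# starting at 0 and not exceeding the period, with linear interpolation
# between samples and periodic wrap-around for evaluation and quadrature.

#' Periodic waveform
#'
#' Container for a periodically extended sampled signal (flow or pressure).
#' Times must start at 0, be strictly increasing, and not exceed the period.
#' Evaluation between samples is piecewise linear; the segment from the last
#' sample back to `w(0)` at `t = period` closes the period.
#'
#' @param times sample times in seconds, strictly increasing, `times[1] == 0`.
#' @param values sample values (canonical units unless stated otherwise).
#' @param period signal period in seconds; defaults to the last sample time.
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(seq(0, 1.2, by = 0.1), sin(2 * pi * seq(0, 1.2, by = 0.1) / 1.3),
#'               period = 1.3)
#' waveform_mean(w)
#' @export
waveform <- function(times, values, period = NULL) {
  if (length(times) < 2L)
    stop("waveform needs at least 2 samples, got ", length(times))
  if (length(times) != length(values))
    stop("times and values differ in length")
  if (anyNA(times) || anyNA(values))
    stop("waveform contains NA samples")
  if (times[1L] != 0)
    stop("waveform times must start at 0, got ", times[1L])
  if (any(diff(times) <= 0))
    stop("waveform times must be strictly increasing (first violation at row ",
         which(diff(times) <= 0)[1L] + 1L, ")")
  if (is.null(period)) period <- times[length(times)]
  if (!is.numeric(period) || period <= 0)
    stop("period must be a positive number")
  if (times[length(times)] > period + 1e-12 * period)
    stop("last sample time exceeds the period")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = as.numeric(period)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  m <- waveform_metrics(x)
  cat(sprintf("<waveform> %d samples, period %.4g s, mean %.6g, range [%.6g, %.6g]\n",
              length(x$times), x$period, m$mean, m$min, m$peak))
  invisible(x)
}

#' Evaluate a waveform at arbitrary times
#'
#' Periodic piecewise-linear evaluation: `w(t) = w(t mod period)`.
#'
#' @param w a [waveform()].
#' @param t numeric vector of times (seconds, any real values).
#' @return Numeric vector of interpolated values.
#' @export
waveform_eval <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  tm <- t %% w$period
  # closed grid over one period: append the wrap point (period, values[1])
  xs <- w$times
  ys <- w$values
  if (xs[length(xs)] < w$period) {
    xs <- c(xs, w$period)
    ys <- c(ys, ys[1L])
  } else {
    # last sample sits exactly on the period boundary; force continuity
    ys[length(ys)] <- ys[1L]
  }
  stats::approx(xs, ys, xout = tm, rule = 2)$y
}

# Closed one-period grid (times including the wrap point at t = period).
wf_closed <- function(w) {
  xs <- w$times
  ys <- w$values
  if (xs[length(xs)] < w$period) {
    xs <- c(xs, w$period)
    ys <- c(ys, ys[1L])
  } else {
    ys[length(ys)] <- ys[1L]
  }
  list(times = xs, values = ys)
}

#' Cycle mean, extremes and pulse of a waveform
#'
#' `waveform_mean()` integrates one period with the trapezoid rule on the
#' periodic extension (the wrap-around segment from the last sample back to
#' the first is included) and divides by the period — exact for piecewise
#' linear signals. `waveform_metrics()` additionally reports the per-period
#' extremes and the pulse (peak minus minimum), the convention used for
#' pulse pressure.
#'
#' @param w a [waveform()].
#' @return `waveform_mean`: scalar mean. `waveform_metrics`: list with
#'   `mean`, `peak`, `min`, `pulse`.
#' @examples
#' tt <- seq(0, 1.25, by = 0.05)
#' w <- waveform(tt, rep(5, length(tt)), period = 1.3)
#' waveform_mean(w)            # 5
#' waveform_metrics(w)$pulse   # 0
#' @export
waveform_mean <- function(w) {
  stopifnot(inherits(w, "waveform"))
  g <- wf_closed(w)
  sum(diff(g$times) * (head_(g$values) + tail_(g$values)) / 2) / w$period
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1L]

#' @rdname waveform_mean
#' @export
waveform_metrics <- function(w) {
  stopifnot(inherits(w, "waveform"))
  pk <- max(w$values)
  mn <- min(w$values)
  list(mean = waveform_mean(w), peak = pk, min = mn, pulse = pk - mn)
}

#' Resample a waveform onto a uniform grid
#'
#' @param w a [waveform()].
#' @param n number of uniform samples over one period.
#' @return A new [waveform()] sampled at `n` points spaced `period / n`.
#' @export
waveform_resample <- function(w, n) {
  stopifnot(inherits(w, "waveform"), n >= 2L)
  tt <- seq(0, w$period, length.out = n + 1L)[seq_len(n)]
  waveform(tt, waveform_eval(w, tt), period = w$period)
}

#' Read and write waveform CSV files
#'
#' The format is a two-column CSV with header `time_s,value`, optionally
#' preceded by comment lines `# period=<seconds>` and
#' `# units=mmHg|mL_per_s`. Values are converted to canonical units on
#' read when a units comment is present. Without a period comment the
#' period is taken as the last sample time.
#'
#' @param path file path.
#' @param w a [waveform()] (values in canonical units).
#' @return `read_waveform_csv` returns a [waveform()];
#'   `write_waveform_csv` invisibly returns `path`.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("no such waveform file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty waveform file: ", path)
  hdr <- grepl("^\\s*#", lines)
  period <- NA_real_
  units <- "canonical"
  for (h in lines[hdr]) {
    if (grepl("period\\s*=", h))
      period <- as.numeric(sub(".*period\\s*=\\s*([0-9.eE+-]+).*", "\\1", h))
    if (grepl("units\\s*=", h))
      units <- trimws(sub(".*units\\s*=\\s*([A-Za-z_]+).*", "\\1", h))
  }
  body <- lines[!hdr]
  if (length(body) < 2L) stop("waveform file has no data rows: ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time_s", "value") %in% names(df)))
    stop("waveform CSV must have columns time_s,value")
  if (anyNA(df$time_s) || anyNA(df$value)) {
    bad <- which(is.na(df$time_s) | is.na(df$value))[1L]
    stop("NA in waveform file at data row ", bad)
  }
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    stop("non-increasing time in waveform file at data row ", bad)
  }
  vals <- switch(units,
                 canonical = df$value,
                 mmHg      = mmhg_to_canonical(df$value),
                 mL_per_s  = ml_per_s_to_canonical(df$value),
                 stop("unknown units comment: ", units))
  waveform(df$time_s, vals, period = if (is.na(period)) NULL else period)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  # %.17g guarantees binary round-trip of doubles through the text file
  writeLines(c(sprintf("# period=%.17g", w$period),
               "time_s,value",
               sprintf("%.17g,%.17g", w$times, w$values)),
             path)
  invisible(path)
}
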