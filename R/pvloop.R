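# Pressure-volume loop extraction and stroke-work quantification.

#' Pressure-volume loop of a converged cycle
#'
#' Builds the closed (V, P) polygon traced by the ventricle over one
#' converged cardiac cycle: filling at low pressure, isovolumetric
#' contraction, ejection at high pressure, isovolumetric relaxation. The
#' input must be cyclically converged: the volume mismatch between cycle
#' start and end must be below 1 % of the volume excursion.
#'
#' @param x a `heart_solution`, or a numeric volume vector.
#' @param P ventricular pressures matching `x` when `x` is a plain vector.
#' @return Object of class `pv_loop` with fields `V` and `P` (one point per
#'   time sample, implicitly closed).
#' @export
pv_loop <- function(x, P = NULL) {
  if (inherits(x, "heart_solution")) {
    V <- x$V
    P <- x$P_LV
  } else {
    V <- x
    if (is.null(P) || length(P) != length(V))
      stop("pv_loop needs matching V and P vectors")
  }
  excursion <- max(V) - min(V)
  if (excursion > 0 &&
      abs(V[length(V)] - V[1L]) > 0.01 * excursion)
    stop("pv_loop input is not cyclically converged: |V(0) - V(T)| = ",
         signif(abs(V[length(V)] - V[1L]), 4), " exceeds 1% of the ",
         signif(excursion, 4), " volume excursion")
  structure(list(V = as.numeric(V), P = as.numeric(P)), class = "pv_loop")
}

#' @export
print.pv_loop <- function(x, ...) {
  w <- stroke_work(x)
  cat(sprintf("<pv_loop> %d points, volume excursion %.1f mL, stroke work %.3f J\n",
              length(x$V), (max(x$V) - min(x$V)) / 1000, w$work_J))
  invisible(x)
}

#' @export
plot.pv_loop <- function(x, ...) {
  graphics::plot(x$V / 1000, canonical_to_mmhg(x$P), type = "l",
                 xlab = "Ventricular volume (mL)",
                 ylab = "Ventricular pressure (mmHg)", ...)
  invisible(x)
}

#' Stroke work as the area of the pressure-volume loop
#'
#' Shoelace area of the closed PV polygon, oriented so that a physiological
#' loop (ejection at high pressure, filling at low pressure) yields
#' positive work. Reported in canonical units (g mm^2/s^2) and joules.
#'
#' @param loop a [pv_loop()].
#' @return List with `work` (canonical) and `work_J` (joule).
#' @examples
#' # rectangular loop: 94 mL excursion at a 100 mmHg pressure difference
#' V <- c(36000, 130000, 130000, 36000)
#' P <- mmhg_to_canonical(c(105, 105, 5, 5))
#' stroke_work(structure(list(V = V, P = P), class = "pv_loop"))$work_J
#' @export
stroke_work <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  V <- loop$V
  P <- loop$P
  Vn <- c(V[-1L], V[1L])
  Pn <- c(P[-1L], P[1L])
  signed <- sum(V * Pn - Vn * P) / 2
  w <- abs(signed)
  list(work = w, work_J = canonical_to_joule(w))
}

#' Relative change between two stroke works
#'
#' Percent change of `w2` relative to `w1`, the quantity used to express a
#' stroke-work increase under a raised afterload.
#'
#' @param w1,w2 stroke works (either the list returned by [stroke_work()]
#'   or plain numbers in the same units).
#' @return Signed percent change `100 * (w2 - w1) / w1`.
#' @export
stroke_work_change <- function(w1, w2) {
  g <- function(w) if (is.list(w)) w$work else w
  100 * (g(w2) - g(w1)) / g(w1)
}
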