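# Three-element (RCR) Windkessel outlet model. The interface pressure seen
# by the network is P = Rp*Q + Pc, and the mid (capacitor) pressure obeys
# C dPc/dt = Q - (Pc - Pd)/Rd, with Pd the distal reference (ground)
# pressure. Time integration is backward Euler, which is unconditionally
# stable and linear in Q — the property the network solver exploits.

#' Three-element Windkessel parameters
#'
#' @param Rp proximal resistance, g/(mm^4 s), > 0.
#' @param C compliance, mm^4 s^2/g, > 0.
#' @param Rd distal resistance, g/(mm^4 s), > 0.
#' @param Pd distal reference (ground) pressure, canonical units, >= 0.
#'   Defaults to 0.
#' @return Object of class `windkessel_params`.
#' @examples
#' wk <- windkessel_params(Rp = 0.80, C = 6.10, Rd = 4.53)
#' wk_interface_pressure(wk, Pc = 0, Q = 1000)   # 800
#' @export
windkessel_params <- function(Rp, C, Rd, Pd = 0) {
  stopifnot(is.numeric(Rp), Rp > 0, is.numeric(C), C > 0,
            is.numeric(Rd), Rd > 0, is.numeric(Pd), Pd >= 0)
  structure(list(Rp = Rp, C = C, Rd = Rd, Pd = Pd),
            class = "windkessel_params")
}

#' Windkessel interface pressure
#'
#' Pressure seen by the vessel at the outlet face: `P = Rp * Q + Pc`.
#'
#' @param params a [windkessel_params()].
#' @param Pc current capacitor (mid) pressure, canonical units.
#' @param Q flow into the outlet, mm^3/s.
#' @return Interface pressure, canonical units.
#' @export
wk_interface_pressure <- function(params, Pc, Q) {
  stopifnot(inherits(params, "windkessel_params"), is.finite(Pc))
  params$Rp * Q + Pc
}

#' Advance the Windkessel capacitor pressure by one implicit step
#'
#' Backward-Euler update of `C dPc/dt = Q - (Pc - Pd)/Rd` with the flow held
#' at its end-of-step value. Unconditionally stable for any `dt`.
#'
#' @inheritParams wk_interface_pressure
#' @param dt time step, s, > 0.
#' @return Updated capacitor pressure.
#' @export
wk_step <- function(params, Pc, Q, dt) {
  stopifnot(inherits(params, "windkessel_params"), dt > 0)
  a <- dt / (params$Rd * params$C)
  (Pc + (dt / params$C) * Q + a * params$Pd) / (1 + a)
}

# Affine reduction of the implicitly stepped outlet: over one backward-Euler
# step the new capacitor pressure is Pc' = a + b*Q, hence the interface
# pressure is P = (Rp + b)*Q + a. Used by the network assembler.
wk_affine <- function(params, Pc, dt) {
  k <- dt / (params$Rd * params$C)
  denom <- 1 + k
  list(a = (Pc + k * params$Pd) / denom,
       b = (dt / params$C) / denom)
}

#' Cycle-mean interface pressure of a periodic Windkessel
#'
#' At cyclic convergence the capacitor stores no net charge over a period,
#' so the mean interface pressure obeys the purely resistive identity
#' `mean(P) = mean(Q) * (Rp + Rd) + Pd`. Serves as an analytic oracle for
#' the time-stepped solution.
#'
#' @param params a [windkessel_params()].
#' @param Q a periodic flow [waveform()].
#' @return Mean interface pressure, canonical units.
#' @export
wk_periodic_mean_identity <- function(params, Q) {
  stopifnot(inherits(params, "windkessel_params"), inherits(Q, "waveform"))
  waveform_mean(Q) * (params$Rp + params$Rd) + params$Pd
}

#' Time-integrate a Windkessel outlet driven by a flow waveform
#'
#' Steps the outlet over `n_cycles` periods of the driving flow and returns
#' the interface-pressure waveform of the final cycle, for checking cyclic
#' behaviour against [wk_periodic_mean_identity()].
#'
#' @param params a [windkessel_params()].
#' @param Q a periodic flow [waveform()].
#' @param dt step size in seconds.
#' @param n_cycles number of periods to integrate.
#' @param Pc0 initial capacitor pressure; defaults to the mean-flow steady
#'   state so that start-up transients are short.
#' @return A pressure [waveform()] over the final cycle.
#' @export
wk_integrate <- function(params, Q, dt = 1e-3, n_cycles = 6,
                         Pc0 = NULL) {
  stopifnot(inherits(Q, "waveform"))
  if (is.null(Pc0))
    Pc0 <- params$Pd + waveform_mean(Q) * params$Rd
  n_per <- max(2L, round(Q$period / dt))
  dt <- Q$period / n_per
  Pc <- Pc0
  last <- numeric(n_per)
  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(n_per)) {
      t1 <- (i) * dt
      q1 <- waveform_eval(Q, t1)
      Pc <- wk_step(params, Pc, q1, dt)
      if (cyc == n_cycles) last[i] <- wk_interface_pressure(params, Pc, q1)
    }
  }
  waveform(seq(0, by = dt, length.out = n_per), c(last[n_per], last[-n_per]),
           period = Q$period)
}

#' Outlet registry of tuned RCR parameters
#'
#' Loads the packaged registry of three-element Windkessel parameters for
#' the 18 branch outlets of the aortic model (right/left carotid and
#' subclavian, visceral, renal, sacral and iliac vessels), as tuned to give
#' physiological flow and pressure waveforms. Units: Rp and Rd in
#' g/(mm^4 s), C in mm^4 s^2/g; the reference pressure Pd defaults to 0.
#'
#' @param path optional CSV with columns `name,Rp,C,Rd` to load instead of
#'   the packaged registry.
#' @return Named list of [windkessel_params()], class `outlet_registry`.
#' @examples
#' reg <- load_table4_registry()
#' length(reg)        # 18
#' reg[["RCCA"]]$Rp   # 0.80
#' @export
load_table4_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "outlet_rcr.csv", package = "aorta0d",
                        mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "Rp", "C", "Rd")
  if (!all(need %in% names(df)))
    stop("outlet registry must have columns name,Rp,C,Rd")
  if (anyDuplicated(df$name))
    stop("duplicate outlet name in registry: ",
         df$name[duplicated(df$name)][1L])
  if (is.null(path) || nrow(df) != 18L) {
    # the packaged registry must carry exactly the 18 printed rows
    if (basename(path) == "outlet_rcr.csv" && nrow(df) != 18L)
      stop("packaged outlet registry corrupted: expected 18 rows, found ",
           nrow(df))
  }
  reg <- stats::setNames(
    lapply(seq_len(nrow(df)),
           function(i) windkessel_params(df$Rp[i], df$C[i], df$Rd[i])),
    df$name)
  structure(reg, class = c("outlet_registry", "list"))
}
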