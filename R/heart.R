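# Lumped-parameter left heart: a constant-pressure left atrium feeding,
# through a mitral valve (diode with resistance and inductance), a
# time-varying elastance ventricle that ejects through an aortic valve
# (diode with resistance and inductance) into an afterload. A viscous loss
# term with resistance R_LV = k_LV * P_LV makes the ejection pressure drop
# k_LV * P_LV * Q_LV. Valves close instantly on an adverse gradient and
# flow is clamped at zero — back flow is precluded by construction.

#' Heart model parameters
#'
#' Bundles the elastance, valve and ventricle parameters of the lumped left
#' heart. All values in canonical g-mm-s units.
#'
#' @param period cardiac period T, s.
#' @param t_max time from cycle start to maximum elastance, s.
#' @param t_relax duration of the elastance relaxation phase, s.
#' @param E_max,E_min maximum and minimum elastance, g/(mm^4 s^2).
#' @param R_av,L_av aortic valve resistance g/(mm^4 s) and inductance g/mm^4.
#' @param R_mv,L_mv mitral valve resistance and inductance.
#' @param k_LV viscous-loss constant, s/mm^3; the instantaneous ventricular
#'   resistance is `k_LV * P_LV`.
#' @param V_u unstressed ventricular volume, mm^3.
#' @param V_ed end-diastolic (initial) volume, mm^3.
#' @param P_LA constant atrial preload pressure, canonical units.
#' @return Object of class `heart_params`.
#' @seealso [load_table5_heart()] for the packaged parameter sets.
#' @export
heart_params <- function(period, t_max, t_relax, E_max, E_min,
                         R_av, L_av, R_mv, L_mv, k_LV,
                         V_u, V_ed, P_LA) {
  stopifnot(period > 0, t_max > 0, t_relax > 0, t_max + t_relax <= period,
            E_min > 0, E_max > E_min,
            R_av >= 0, L_av >= 0, R_mv >= 0, L_mv >= 0, k_LV >= 0,
            V_u >= 0, V_ed > V_u, P_LA > 0)
  structure(list(period = period, t_max = t_max, t_relax = t_relax,
                 E_max = E_max, E_min = E_min,
                 R_av = R_av, L_av = L_av, R_mv = R_mv, L_mv = L_mv,
                 k_LV = k_LV, V_u = V_u, V_ed = V_ed, P_LA = P_LA),
            class = "heart_params")
}

#' Packaged heart parameter sets
#'
#' Loads the tuned heart model parameters for the dissected or undissected
#' aortic model from the packaged table.
#'
#' @param model `"dissected"` or `"undissected"`.
#' @return A [heart_params()] object.
#' @export
load_table5_heart <- function(model = c("dissected", "undissected")) {
  model <- match.arg(model)
  path <- system.file("extdata", "heart_params.csv", package = "aorta0d",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  v <- stats::setNames(df[[model]], df$parameter)
  heart_params(period = v[["period"]],
               t_max = v[["time_to_max_elastance"]],
               t_relax = v[["time_to_relaxation"]],
               E_max = v[["max_elastance"]],
               E_min = v[["min_elastance"]],
               R_av = v[["aortic_valve_resistance"]],
               L_av = v[["aortic_valve_inductance"]],
               R_mv = v[["mitral_valve_resistance"]],
               L_mv = v[["mitral_valve_inductance"]],
               k_LV = v[["ventricular_resistance_k"]],
               V_u = v[["unstressed_volume"]],
               V_ed = v[["end_diastolic_volume"]],
               P_LA = v[["preload"]])
}

#' Time-varying ventricular elastance
#'
#' Piecewise-cosine activation: a half-cosine rise from `E_min` at t = 0 to
#' `E_max` at `t_max`, a half-cosine fall back to `E_min` over `t_relax`,
#' and `E_min` for the rest of the cycle. C0-continuous and periodic in the
#' cardiac period.
#'
#' @param t time in seconds (vectorised); evaluated modulo the period.
#' @param p a [heart_params()] (only the elastance fields are used).
#' @return Elastance values, g/(mm^4 s^2).
#' @examples
#' hp <- load_table5_heart("dissected")
#' elastance(0, hp)          # E_min
#' elastance(hp$t_max, hp)   # E_max
#' @export
elastance <- function(t, p) {
  tt <- t %% p$period
  amp <- (p$E_max - p$E_min) / 2
  out <- rep(p$E_min, length(tt))
  rise <- tt <= p$t_max
  out[rise] <- p$E_min + amp * (1 - cos(pi * tt[rise] / p$t_max))
  fall <- tt > p$t_max & tt <= p$t_max + p$t_relax
  out[fall] <- p$E_min + amp * (1 + cos(pi * (tt[fall] - p$t_max) / p$t_relax))
  out
}

#' Ventricular pressure from the elastance relation
#'
#' `P_LV = E(t) * (V - V_u)`.
#'
#' @param V ventricular volume, mm^3; must exceed the unstressed volume.
#' @param t time, s.
#' @param p a [heart_params()].
#' @return Pressure in canonical units.
#' @export
lv_pressure <- function(V, t, p) {
  if (any(V <= p$V_u))
    stop("ventricular volume at or below the unstressed volume")
  elastance(t, p) * (V - p$V_u)
}

#' Viscous ejection pressure loss
#'
#' The pressure drop across the time-varying ventricular resistance
#' `R_LV = k_LV * P_LV`, i.e. `dP = k_LV * P_LV * Q_LV`. Non-negative for
#' forward flow at positive pressure.
#'
#' @param P_LV ventricular pressure, canonical units.
#' @param Q_LV outflow through the aortic valve, mm^3/s, >= 0.
#' @param k_LV loss constant, s/mm^3.
#' @return Pressure drop, canonical units.
#' @export
viscous_loss <- function(P_LV, Q_LV, k_LV) {
  if (any(Q_LV < 0)) stop("viscous_loss expects non-negative flow")
  k_LV * P_LV * Q_LV
}

# Solve the implicit per-step flow equations for the given valve states.
# Unknowns are the open-valve flows; the ventricular volume and pressure
# are eliminated through V1 = V0 + dt*(Qm - Qa). Newton with analytic
# Jacobian; the only nonlinearity is the k_LV * P_LV * Q_av loss term.
heart_solve_flows <- function(av_open, mv_open, V0, Qa0, Qm0, E1, p,
                              down_a, down_b, dt) {
  Qa <- if (av_open) max(Qa0, 0) else 0
  Qm <- if (mv_open) max(Qm0, 0) else 0
  scale <- max(p$P_LA, abs(down_a), 1)
  for (it in seq_len(25L)) {
    V1 <- V0 + dt * (Qm - Qa)
    P  <- E1 * (V1 - p$V_u)
    ra <- rm <- 0
    if (av_open)
      ra <- (p$L_av / dt) * (Qa - Qa0) -
        (P * (1 - p$k_LV * Qa) - p$R_av * Qa - (down_a + down_b * Qa))
    if (mv_open)
      rm <- (p$L_mv / dt) * (Qm - Qm0) - (p$P_LA - P - p$R_mv * Qm)
    if (max(abs(ra), abs(rm)) < 1e-10 * scale) break
    if (av_open && mv_open) {
      Jaa <- p$L_av / dt + E1 * dt * (1 - p$k_LV * Qa) + p$k_LV * P +
        p$R_av + down_b
      Jam <- -E1 * dt * (1 - p$k_LV * Qa)
      Jma <- -E1 * dt
      Jmm <- p$L_mv / dt + E1 * dt + p$R_mv
      det <- Jaa * Jmm - Jam * Jma
      Qa <- Qa - ( Jmm * ra - Jam * rm) / det
      Qm <- Qm - (-Jma * ra + Jaa * rm) / det
    } else if (av_open) {
      Jaa <- p$L_av / dt + E1 * dt * (1 - p$k_LV * Qa) + p$k_LV * P +
        p$R_av + down_b
      Qa <- Qa - ra / Jaa
    } else if (mv_open) {
      Jmm <- p$L_mv / dt + E1 * dt + p$R_mv
      Qm <- Qm - rm / Jmm
    } else break
  }
  list(Qa = Qa, Qm = Qm)
}

#' Advance the heart model by one implicit time step
#'
#' Backward-Euler update of ventricular volume and valve flows. Valve
#' states are re-evaluated after each sub-solve: a valve closes (flow
#' clamped to exactly zero) as soon as its solved flow would become
#' negative, and opens when the pressure gradient across it turns
#' favourable. The downstream (aortic-root) pressure is supplied as an
#' affine map `P_down = a + b * Q_av`, which is how an implicitly stepped
#' Windkessel or network node presents itself; a constant pressure is the
#' special case `b = 0`.
#'
#' @param state list with `V`, `Q_av`, `Q_mv`, `av_open`, `mv_open`.
#' @param t time at the beginning of the step, s.
#' @param dt step size, s, > 0.
#' @param p a [heart_params()].
#' @param downstream either a single pressure value or a list `list(a=, b=)`
#'   describing `P_down = a + b * Q_av` at the end of the step.
#' @return Updated state list, with `P_LV` and `P_ao` added.
#' @export
heart_step <- function(state, t, dt, p, downstream) {
  stopifnot(dt > 0)
  if (is.numeric(downstream)) downstream <- list(a = downstream, b = 0)
  t1 <- t + dt
  E1 <- elastance(t1, p)
  av <- state$av_open
  mv <- state$mv_open
  for (sw in seq_len(6L)) {
    fl <- heart_solve_flows(av, mv, state$V, state$Q_av, state$Q_mv, E1, p,
                            downstream$a, downstream$b, dt)
    V1 <- state$V + dt * (fl$Qm - fl$Qa)
    P1 <- E1 * (V1 - p$V_u)
    # Aortic diode: ideal-diode behaviour -- closes when the solved flow
    # would reverse, which with the dominant viscous-loss resistance means
    # the flow has already decayed to zero; back flow is precluded.
    # Mitral diode: closes instantly on an adverse pressure gradient
    # (P_LV rising through the preload), which pins the end-diastolic
    # volume at the diastolic equilibrium P_LA / E_min.
    grad_mv <- p$P_LA - P1
    av_new <- av
    mv_new <- mv
    if (av && fl$Qa < 0) av_new <- FALSE
    if (!av && P1 > downstream$a) av_new <- TRUE
    if (mv && (grad_mv < 0 || fl$Qm < 0)) mv_new <- FALSE
    if (!mv && grad_mv > 0) mv_new <- TRUE
    if (identical(av_new, av) && identical(mv_new, mv)) break
    av <- av_new
    mv <- mv_new
  }
  Qa <- max(fl$Qa, 0)
  Qm <- max(fl$Qm, 0)
  V1 <- state$V + dt * (Qm - Qa)
  P1 <- E1 * (V1 - p$V_u)
  list(V = V1, Q_av = Qa, Q_mv = Qm, av_open = av && Qa >= 0,
       mv_open = mv && Qm >= 0, P_LV = P1,
       P_ao = downstream$a + downstream$b * Qa)
}

#' Simulate the heart model against a Windkessel afterload
#'
#' Couples the lumped heart to a single three-element Windkessel and steps
#' the closed loop to cyclic convergence. Convergence is declared when the
#' per-cycle stroke volume and cycle-mean aortic pressure both change by
#' less than `tol` (relative) between consecutive cycles.
#'
#' @param p a [heart_params()].
#' @param afterload a [windkessel_params()].
#' @param dt time step, s (default 1 ms).
#' @param max_cycles cycle cap before a convergence error is raised.
#' @param tol relative cycle-to-cycle tolerance.
#' @param Pc0 initial Windkessel capacitor pressure; default 90 mmHg.
#' @return Object of class `heart_solution`: final-cycle arrays `times`,
#'   `V`, `P_LV`, `Q_av`, `Q_mv`, `P_ao`, the per-cycle `trace` data frame,
#'   achieved `stroke_volume`, `mean_flow`, `peak_flow`, and `cycles`.
#' @examples
#' \donttest{
#' hp <- load_table5_heart("dissected")
#' af <- load_single_rcr_afterload()
#' sol <- simulate_heart(hp, af)
#' sol$stroke_volume / 1000   # mL per beat
#' }
#' @export
simulate_heart <- function(p, afterload, dt = 1e-3, max_cycles = 30L,
                           tol = 1e-3, Pc0 = 90 * MMHG) {
  stopifnot(inherits(p, "heart_params"), inherits(afterload, "windkessel_params"))
  n_per <- max(2L, round(p$period / dt))
  dt <- p$period / n_per
  state <- list(V = p$V_ed, Q_av = 0, Q_mv = 0,
                av_open = FALSE, mv_open = FALSE)
  Pc <- Pc0
  trace <- NULL
  arr <- function() list(V = numeric(n_per), P_LV = numeric(n_per),
                         Q_av = numeric(n_per), Q_mv = numeric(n_per),
                         P_ao = numeric(n_per))
  prev_sv <- NA_real_
  prev_pm <- NA_real_
  converged <- FALSE
  cyc_final <- NA_integer_
  for (cyc in seq_len(max_cycles)) {
    a <- arr()
    for (i in seq_len(n_per)) {
      t0 <- (i - 1L) * dt
      aff <- wk_affine(afterload, Pc, dt)
      down <- list(a = aff$a, b = afterload$Rp + aff$b)
      state <- heart_step(state, t0, dt, p, down)
      Pc <- aff$a + aff$b * state$Q_av
      a$V[i] <- state$V; a$P_LV[i] <- state$P_LV
      a$Q_av[i] <- state$Q_av; a$Q_mv[i] <- state$Q_mv
      a$P_ao[i] <- state$P_ao
    }
    sv <- sum(a$Q_av) * dt
    pm <- mean(a$P_ao)
    pk <- max(a$Q_av)
    trace <- rbind(trace, data.frame(cycle = cyc, stroke_volume = sv,
                                     mean_p_ao = pm, peak_flow = pk))
    if (cyc > 1L &&
        abs(sv - prev_sv) < tol * max(abs(prev_sv), 1e-12) &&
        abs(pm - prev_pm) < tol * max(abs(prev_pm), 1e-12)) {
      converged <- TRUE
      cyc_final <- cyc
      break
    }
    prev_sv <- sv
    prev_pm <- pm
  }
  if (!converged)
    stop("heart simulation failed to reach cyclic convergence in ",
         max_cycles, " cycles (last stroke volumes: ",
         paste(signif(utils::tail(trace$stroke_volume, 3), 5), collapse = ", "),
         ")")
  structure(list(times = seq_len(n_per) * dt, dt = dt, period = p$period,
                 V = a$V, P_LV = a$P_LV, Q_av = a$Q_av, Q_mv = a$Q_mv,
                 P_ao = a$P_ao,
                 stroke_volume = sum(a$Q_av) * dt,
                 mean_flow = sum(a$Q_av) * dt / p$period,
                 peak_flow = max(a$Q_av),
                 cycles = cyc_final, trace = trace, params = p,
                 afterload = afterload),
            class = "heart_solution")
}

#' @export
print.heart_solution <- function(x, ...) {
  cat(sprintf(paste0("<heart_solution> %d cycles to convergence; SV %.1f mL, ",
                     "mean CO %.2f L/min, peak flow %.0f mm^3/s\n"),
              x$cycles, x$stroke_volume / 1000,
              x$mean_flow * 60 / 1e6, x$peak_flow))
  invisible(x)
}

#' Packaged single-Windkessel systemic afterload
#'
#' A single lumped RCR element standing in for the whole systemic
#' circulation, used as the reference afterload of the tuning loop.
#'
#' @param scale multiply both resistances by this factor (compliance
#'   unchanged), e.g. to emulate an increased afterload.
#' @return A [windkessel_params()].
#' @export
load_single_rcr_afterload <- function(scale = 1) {
  path <- system.file("extdata", "single_rcr_afterload.csv",
                      package = "aorta0d", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  windkessel_params(df$Rp[1] * scale, df$C[1], df$Rd[1] * scale)
}
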