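# Monolithic implicit solver for the 0D network. Unknowns are the nodal
# pressures; each element contributes a flow that is affine in the end
# pressures after backward-Euler elimination of its internal state
# (inductive flow history, Windkessel capacitor pressure). The nodal
# flow-balance system is therefore linear unless quadratic orifice losses
# are enabled, in which case the element conductances are relinearised
# within a Newton loop each step. Cycles are advanced until the cycle-mean
# pressure and flow at every outlet change by less than `tol` between
# consecutive cycles.

# DC (mean-flow) solve of the purely resistive network; used to initialise
# all states so that the start-up transient is short.
network_dc_solve <- function(topo, Q_mean) {
  n <- length(topo$nodes)
  A <- matrix(0, n, n)
  b <- numeric(n)
  g <- 1 / topo$elements$R
  for (k in seq_along(g)) {
    i <- topo$from_i[k]; j <- topo$to_i[k]
    A[i, i] <- A[i, i] + g[k]; A[j, j] <- A[j, j] + g[k]
    A[i, j] <- A[i, j] - g[k]; A[j, i] <- A[j, i] - g[k]
  }
  for (k in seq_len(nrow(topo$outlets))) {
    wk <- topo$outlet_params[[k]]
    i <- topo$outlets$node_i[k]
    gw <- 1 / (wk$Rp + wk$Rd)
    A[i, i] <- A[i, i] + gw
    b[i] <- b[i] + gw * wk$Pd
  }
  b[topo$inlet_i] <- b[topo$inlet_i] + Q_mean
  p <- solve(A, b)
  Qe <- g * (p[topo$from_i] - p[topo$to_i])
  Qout <- vapply(seq_len(nrow(topo$outlets)), function(k) {
    wk <- topo$outlet_params[[k]]
    (p[topo$outlets$node_i[k]] - wk$Pd) / (wk$Rp + wk$Rd)
  }, numeric(1))
  list(p = p, Qe = Qe, Qout = Qout)
}

#' Solve a 0D network to cyclic convergence
#'
#' Advances the assembled network with implicit (backward-Euler) steps,
#' driven either by a prescribed inflow waveform or by the lumped heart
#' model coupled monolithically at the inlet node. All states are
#' initialised from a mean-flow resistive solve, so convergence is reached
#' within a few cardiac cycles. Convergence is declared when the relative
#' change of every outlet's cycle-mean pressure and flow between
#' consecutive cycles falls below `tol`.
#'
#' @param topo a [build_network()] topology.
#' @param inlet either a flow [waveform()] (mm^3/s) or a list
#'   `list(heart = heart_params)` to couple the heart model at the inlet.
#' @param dt time step, s (must be <= 1 ms).
#' @param max_cycles cycle cap; reaching it without convergence is an error.
#' @param tol relative cycle-to-cycle convergence tolerance (default 1e-3).
#' @param min_cycles minimum number of cycles to run (default 3).
#' @return Object of class `network_solution` with final-cycle nodal
#'   pressure and element flow waveforms, per-outlet summary, and the
#'   cycle-convergence trace.
#' @examples
#' \donttest{
#' topo <- build_network(fixture_configs()$dissected_baseline)
#' sol <- simulate_network(topo, generate_inflow())
#' lumen_flow_split(sol, 1)
#' }
#' @export
simulate_network <- function(topo, inlet, dt = 1e-3, max_cycles = 10L,
                             tol = 1e-3, min_cycles = 3L) {
  stopifnot(inherits(topo, "network_topology"), dt > 0, dt <= 1e-3 + 1e-12)
  heart_mode <- is.list(inlet) && !inherits(inlet, "waveform") &&
    !is.null(inlet$heart)
  if (heart_mode) {
    hp <- inlet$heart
    stopifnot(inherits(hp, "heart_params"))
    period <- hp$period
  } else {
    stopifnot(inherits(inlet, "waveform"))
    period <- inlet$period
  }
  n_per <- max(2L, round(period / dt))
  dt <- period / n_per
  n <- length(topo$nodes)
  ne <- nrow(topo$elements)
  no <- nrow(topo$outlets)
  el <- topo$elements
  from_i <- topo$from_i
  to_i <- topo$to_i
  nonlinear <- any(el$K > 0)

  # Windkessel affine constants (dt fixed): Pc' = wa(Pc) + wb*Q,
  # interface P = (Rp + wb)*Q + wa  ->  Q = (p_node - wa) / (Rp + wb)
  wk_k <- vapply(topo$outlet_params, function(w) dt / (w$Rd * w$C), numeric(1))
  wk_b <- vapply(topo$outlet_params, function(w)
    (dt / w$C) / (1 + dt / (w$Rd * w$C)), numeric(1))
  wk_Rp <- vapply(topo$outlet_params, function(w) w$Rp, numeric(1))
  wk_Pd <- vapply(topo$outlet_params, function(w) w$Pd, numeric(1))
  g_out <- 1 / (wk_Rp + wk_b)
  out_i <- topo$outlets$node_i

  # initialise states from the DC solve
  Qm0 <- if (heart_mode) 72308 else waveform_mean(inlet)
  dc <- network_dc_solve(topo, Qm0)
  p <- dc$p
  Q_prev <- dc$Qe
  Pc <- wk_Pd + dc$Qout * vapply(topo$outlet_params, function(w) w$Rd,
                                 numeric(1))
  if (heart_mode)
    hstate <- list(V = hp$V_ed, Q_av = 0, Q_mv = 0,
                   av_open = FALSE, mv_open = FALSE)

  gL <- el$L / dt
  g_lin <- 1 / (gL + el$R)   # conductance of linear elements

  assemble_A <- function(g_e) {
    A <- matrix(0, n, n)
    for (k in seq_len(ne)) {
      i <- from_i[k]; j <- to_i[k]
      A[i, i] <- A[i, i] + g_e[k]; A[j, j] <- A[j, j] + g_e[k]
      A[i, j] <- A[i, j] - g_e[k]; A[j, i] <- A[j, i] - g_e[k]
    }
    for (k in seq_len(no)) {
      i <- out_i[k]
      A[i, i] <- A[i, i] + g_out[k]
    }
    diag(A) <- diag(A) + topo$node_C / dt
    A
  }

  Ainv <- NULL
  if (!nonlinear) Ainv <- solve(assemble_A(g_lin))

  pm_prev <- NULL
  qm_prev <- NULL
  trace <- NULL
  converged <- FALSE
  pc_snaps <- list()   # cycle-end capacitor states for Aitken acceleration
  Pmat <- matrix(0, n_per, n)
  Qmat <- matrix(0, n_per, ne)
  Qout_wf <- matrix(0, n_per, no)
  Qin_rec <- numeric(n_per)
  Hrec <- if (heart_mode)
    list(V = numeric(n_per), P_LV = numeric(n_per), Q_mv = numeric(n_per))
  else NULL

  for (cyc in seq_len(max_cycles)) {
    for (i_t in seq_len(n_per)) {
      t1 <- i_t * dt
      wa <- (Pc + wk_k * wk_Pd) / (1 + wk_k)
      # RHS without the inlet flow
      b0 <- numeric(n)
      s_e <- gL * Q_prev * g_lin     # inductive history source
      if (any(s_e != 0)) {
        for (k in which(s_e != 0)) {
          b0[from_i[k]] <- b0[from_i[k]] - s_e[k]
          b0[to_i[k]] <- b0[to_i[k]] + s_e[k]
        }
      }
      b0[out_i] <- b0[out_i] + g_out * wa
      b0 <- b0 + (topo$node_C / dt) * p

      if (heart_mode) {
        c1 <- Ainv[topo$inlet_i, topo$inlet_i]
        c0 <- drop(Ainv[topo$inlet_i, ] %*% b0)
        hstate <- heart_step(hstate, t1 - dt, dt, hp,
                             list(a = c0, b = c1))
        Qin <- hstate$Q_av
      } else {
        Qin <- waveform_eval(inlet, t1)
      }
      b <- b0
      b[topo$inlet_i] <- b[topo$inlet_i] + Qin

      if (!nonlinear) {
        p <- drop(Ainv %*% b)
        Qe <- g_lin * (p[from_i] - p[to_i]) + s_e
      } else {
        # Newton: relinearise orifice conductances until pressures settle
        g_e <- g_lin
        for (nit in seq_len(20L)) {
          A <- assemble_A(g_e)
          p_new <- solve(A, b)
          dp <- p_new[from_i] - p_new[to_i]
          # recover orifice flows consistently: R*Q + K*Q|Q| = dp
          Qe <- numeric(ne)
          for (k in seq_len(ne)) {
            if (el$K[k] > 0) {
              s <- sign(dp[k])
              Qe[k] <- s * (-el$R[k] +
                sqrt(el$R[k]^2 + 4 * el$K[k] * abs(dp[k]))) / (2 * el$K[k])
            } else {
              Qe[k] <- g_lin[k] * dp[k] + s_e[k]
            }
          }
          g_new <- ifelse(el$K > 0, 1 / (el$R + 2 * el$K * abs(Qe)), g_lin)
          if (max(abs(p_new - p)) < 1e-9 * max(abs(p_new), 1)) {
            p <- p_new
            break
          }
          p <- p_new
          g_e <- g_new
          if (nit == 20L)
            stop("network Newton failed to converge at t = ",
                 signif((cyc - 1) * period + t1, 6), " s")
        }
      }
      Q_prev <- Qe
      Qout <- g_out * (p[out_i] - wa)
      Pc <- wa + wk_b * Qout
      Pmat[i_t, ] <- p
      Qmat[i_t, ] <- Qe
      Qout_wf[i_t, ] <- Qout
      Qin_rec[i_t] <- Qin
      if (heart_mode) {
        Hrec$V[i_t] <- hstate$V
        Hrec$P_LV[i_t] <- hstate$P_LV
        Hrec$Q_mv[i_t] <- hstate$Q_mv
      }
    }
    # per-outlet cycle means; the mean flow follows from the mean node
    # pressure via the periodic-mean identity of the stepped Windkessel
    pm <- colMeans(Pmat[, out_i, drop = FALSE])
    qm <- vapply(seq_len(no), function(k) {
      # mean outlet flow from mean node pressure and periodic identity
      (pm[k] - wk_Pd[k]) / (wk_Rp[k] + topo$outlet_params[[k]]$Rd)
    }, numeric(1))
    trace <- rbind(trace, data.frame(cycle = cyc,
                                     max_dp = if (is.null(pm_prev)) NA_real_
                                     else max(abs(pm - pm_prev) /
                                              pmax(abs(pm_prev), 1e-12)),
                                     max_dq = if (is.null(qm_prev)) NA_real_
                                     else max(abs(qm - qm_prev) /
                                              pmax(abs(qm_prev), 1e-12))))
    if (!is.null(pm_prev) && cyc >= min_cycles) {
      rel_p <- max(abs(pm - pm_prev) / pmax(abs(pm_prev), 1e-12))
      rel_q <- max(abs(qm - qm_prev) / pmax(abs(qm_prev), 1e-12))
      if (rel_p < tol && rel_q < tol) {
        converged <- TRUE
        break
      }
    }
    pm_prev <- pm
    qm_prev <- qm
    # capacitor transients decay geometrically from cycle to cycle;
    # componentwise Aitken extrapolation of three consecutive cycle-end
    # states jumps (near-)exactly onto the periodic orbit of the linear
    # state map, repeated every three cycles to squash remaining modes
    pc_snaps <- c(pc_snaps, list(Pc))
    if (length(pc_snaps) == 3L) {
      d1 <- pc_snaps[[2L]] - pc_snaps[[1L]]
      d2 <- pc_snaps[[3L]] - pc_snaps[[2L]]
      den <- d1 - d2
      ok <- abs(den) > 1e-10 * pmax(abs(Pc), 1)
      Pc[ok] <- Pc[ok] + d2[ok]^2 / den[ok]
      pc_snaps <- list()
    }
  }
  if (!converged)
    stop("network failed to reach cyclic convergence in ", max_cycles,
         " cycles (tol ", tol, "); trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))

  times <- seq_len(n_per) * dt
  outlet_summary <- data.frame(
    name = topo$outlets$name,
    node = topo$outlets$node,
    mean_flow = colMeans(Qout_wf),
    mean_pressure = colMeans(Pmat[, out_i, drop = FALSE]),
    stringsAsFactors = FALSE)

  structure(list(times = times, dt = dt, period = period,
                 nodes = topo$nodes,
                 pressures = Pmat, flows = Qmat,
                 elements = el,
                 inflow = Qin_rec,
                 outlet_flows = Qout_wf,
                 outlet_summary = outlet_summary,
                 heart = Hrec,
                 cycles = cyc, trace = trace,
                 topology = topo),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf(paste0("<network_solution> '%s': %d cycles to convergence, ",
                     "inlet mean %.0f mm^3/s, outlet mean sum %.0f mm^3/s\n"),
              x$topology$variant, x$cycles, mean(x$inflow),
              sum(x$outlet_summary$mean_flow)))
  invisible(x)
}

#' Extract a probe waveform from a network solution
#'
#' @param sol a `network_solution`.
#' @param what `"pressure"` for a node or `"flow"` for an element.
#' @param name node or element name.
#' @return A [waveform()] over the final cycle.
#' @export
solution_waveform <- function(sol, what = c("pressure", "flow"), name) {
  what <- match.arg(what)
  if (what == "pressure") {
    i <- match(name, sol$nodes)
    if (is.na(i)) stop("unknown node: ", name)
    v <- sol$pressures[, i]
  } else {
    i <- match(name, sol$elements$name)
    if (is.na(i)) stop("unknown element: ", name)
    v <- sol$flows[, i]
  }
  n <- length(v)
  waveform(c(0, sol$times[-n]), c(v[n], v[-n]), period = sol$period)
}
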