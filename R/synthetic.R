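# Synthetic data generators: a PC-MRI-like aortic inflow waveform, noisy
# per-lumen flow "measurements", and the four packaged network
# configurations (undissected, baseline dissected, maximal and minimal
# tears). Everything is a pure function of its specification and seed.

#' Generate a PC-MRI-like aortic inflow waveform
#'
#' A smooth half-sine systolic pulse of duration
#' `systolic_fraction * period`, an optional negative early-diastolic lobe
#' carrying `backflow_fraction` of the stroke volume, and zero flow for the
#' rest of diastole, sampled at `n_samples` gated phases. The sampled
#' waveform is renormalised so that its trapezoid integral over one period
#' equals the stroke volume exactly.
#'
#' Defaults emulate the measured study conditions: stroke volume 94 mL at
#' a 1.3 s cardiac period (46 BPM gives a cardiac output of 4.3 L/min;
#' the clinically rounded 47 BPM with 94 mL corresponds to 4.4 L/min),
#' 25 gated phases (52 ms temporal resolution), no back flow.
#'
#' @param stroke_volume net ejected volume per beat, mm^3.
#' @param period cardiac period, s.
#' @param systolic_fraction systole duration as a fraction of the period.
#' @param backflow_fraction early-diastolic reverse volume as a fraction of
#'   the stroke volume (>= 0; must be < 1).
#' @param n_samples number of gated phases over one period.
#' @return A flow [waveform()] in mm^3/s.
#' @examples
#' w <- generate_inflow()
#' waveform_mean(w) * w$period   # 94000 exactly
#' @export
generate_inflow <- function(stroke_volume = 94000, period = 1.3,
                            systolic_fraction = 0.33,
                            backflow_fraction = 0, n_samples = 25L) {
  stopifnot(stroke_volume > 0, period > 0,
            systolic_fraction > 0, systolic_fraction < 1,
            backflow_fraction >= 0, n_samples >= 8L)
  if (backflow_fraction >= 1)
    stop("backflow volume must be smaller than the forward volume")
  ts <- systolic_fraction * period
  tb <- min(0.5 * ts, period - ts)          # early-diastolic lobe duration
  fw <- 1 + backflow_fraction               # forward volume multiplier
  A <- pi * stroke_volume * fw / (2 * ts)   # forward half-sine amplitude
  B <- if (backflow_fraction > 0)
    pi * stroke_volume * backflow_fraction / (2 * tb) else 0
  shape <- function(t) {
    q <- numeric(length(t))
    s <- t <= ts
    q[s] <- A * sin(pi * t[s] / ts)
    if (B > 0) {
      d <- t > ts & t <= ts + tb
      q[d] <- -B * sin(pi * (t[d] - ts) / tb)
    }
    q
  }
  tt <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  w <- waveform(tt, shape(tt), period = period)
  # exact renormalisation of the sampled (trapezoid-integrated) volume
  vol <- waveform_mean(w) * period
  if (vol <= 0) stop("degenerate inflow specification: non-positive volume")
  waveform(tt, w$values * (stroke_volume / vol), period = period)
}

#' Generate noisy per-lumen flow measurements
#'
#' Perturbs a reference per-lumen measurement set by multiplicative
#' Gaussian noise and recomputes totals as TL + FL. With `sd = 0` the
#' packaged reference values are returned unchanged. The generator is a
#' pure function of `(spec, seed)`: the global RNG state is left intact.
#'
#' @param reference wide-form measurement data frame (default the packaged
#'   set from [load_lumen_measurements()]).
#' @param sd relative standard deviation of the multiplicative noise.
#' @param seed integer seed.
#' @return Data frame with columns `location`, `Q_TL`, `Q_FL`, `Q_total`.
#' @export
generate_measurements <- function(reference = load_lumen_measurements(),
                                  sd = 0.05, seed = 1L) {
  stopifnot(sd >= 0)
  n <- nrow(reference)
  if (sd == 0) {
    out <- reference
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    out <- reference
    out$Q_TL <- reference$Q_TL * (1 + stats::rnorm(n, sd = sd))
    out$Q_FL <- reference$Q_FL * (1 + stats::rnorm(n, sd = sd))
  }
  out$Q_TL <- pmax(out$Q_TL, 0)
  out$Q_FL <- pmax(out$Q_FL, 0)
  out$Q_total <- out$Q_TL + out$Q_FL
  out
}

# shared geometry of the descending-aorta surrogate (mm). The true lumen is
# made markedly narrower than the false lumen, calibrated once so that the
# baseline thoracic flow split lands near the measured FL-dominant split.
aorta_geometry <- function() {
  list(trunk = data.frame(
         name = c("asc", "arch_a", "arch_b", "desc_thor"),
         from = c("n_inlet", "n_arch1", "n_arch2", "n_thor"),
         to = c("n_arch1", "n_arch2", "n_thor", "n_prox"),
         radius = c(15, 14, 13, 12),
         length = c(60, 40, 40, 30),
         lumen = "trunk", stringsAsFactors = FALSE),
       r_tl = 5.1, r_fl = 7.0, seg_len = 40,
       r_desc = 12,          # undissected descending radius
       r_branch = 3, l_branch = 20,
       septum = 2,           # tear channel length (septum thickness), mm
       area_entry = 135, area_exit = 68, area_secondary = 20)
}

make_chain <- function(prefix, n, from0, radius, seg_len, lumen) {
  nodes <- paste0(prefix, seq_len(n))
  data.frame(name = paste0(prefix, "_seg_", seq_len(n)),
             from = c(from0, nodes[-n]), to = nodes,
             radius = radius, length = seg_len, lumen = lumen,
             stringsAsFactors = FALSE)
}

branch_stubs <- function(map, r, l) {
  # map: named character vector outlet name -> lumen node
  data.frame(name = paste0("stub_", gsub(" ", "_", names(map))),
             from = unname(map),
             to = paste0("b_", gsub(" ", "_", names(map))),
             radius = r, length = l, lumen = "branch",
             stringsAsFactors = FALSE)
}

#' Packaged network configurations
#'
#' Builds the four study configurations of the 0D aortic surrogate:
#' \describe{
#'   \item{undissected}{single descending chain, no tears;}
#'   \item{dissected_baseline}{true- and false-lumen chains with the
#'     primary entry (135 mm^2) and exit (68 mm^2) tears plus 15 secondary
#'     tears (17 in total);}
#'   \item{maximal_tears}{baseline plus two additional thoracic tears
#'     (19 in total);}
#'   \item{minimal_tears}{entry and exit tears only (2).}
#' }
#' All four attach the full 18-outlet registry. Branch vessels perfused
#' from the false lumen (left renal, inferior mesenteric, medial sacral)
#' take off from the false-lumen chain in the dissected variants.
#'
#' @return Named list of configuration lists accepted by [build_network()].
#' @examples
#' n_tears(fixture_configs()$dissected_baseline)  # 17
#' @export
fixture_configs <- function() {
  g <- aorta_geometry()
  upper <- c("RCCA" = "n_arch1", "RSCA" = "n_arch1",
             "LCCA" = "n_arch2", "LSCA" = "n_arch2")
  iliac <- c("L Int Iliac" = "n_dist", "R Int Iliac" = "n_dist",
             "L Ext Iliac" = "n_dist", "R Ext Iliac" = "n_dist")

  # ---- undissected: one descending chain -------------------------------
  chain_u <- make_chain("d", 6, "n_prox", g$r_desc, g$seg_len, "trunk")
  visc_u <- c("Hepatic" = "d4", "Splenic" = "d4", "M Coeliac" = "d4",
              "SMA" = "d4", "R Renal 1" = "d5", "R Renal 2" = "d5",
              "L Renal" = "d5", "IMA" = "d6", "M Sacral 1" = "d6",
              "M Sacral 2" = "d6")
  dist_u <- data.frame(name = "desc_dist", from = "d6", to = "n_dist",
                       radius = g$r_desc, length = 30, lumen = "trunk",
                       stringsAsFactors = FALSE)
  map_u <- c(upper, visc_u, iliac)
  undissected <- list(
    variant = "undissected",
    segments = rbind(g$trunk, chain_u, dist_u,
                     branch_stubs(map_u, g$r_branch, g$l_branch)),
    tears = NULL,
    outlets = data.frame(name = names(map_u),
                         node = paste0("b_", gsub(" ", "_", names(map_u))),
                         stringsAsFactors = FALSE),
    inlet = "n_inlet",
    stations = NULL)

  # ---- dissected variants: TL + FL chains ------------------------------
  chain_t <- make_chain("t", 6, "n_prox", g$r_tl, g$seg_len, "true_lumen")
  # f0 heads the false-lumen chain and is fed only through the entry tear
  chain_f <- make_chain("f", 6, "f0", g$r_fl, g$seg_len, "false_lumen")
  dist_t <- data.frame(name = "desc_dist", from = "t6", to = "n_dist",
                       radius = g$r_desc, length = 30, lumen = "true_lumen",
                       stringsAsFactors = FALSE)
  visc_d <- c("Hepatic" = "t4", "Splenic" = "t4", "M Coeliac" = "t4",
              "SMA" = "t4", "R Renal 1" = "t5", "R Renal 2" = "t5",
              "L Renal" = "f5", "IMA" = "f6", "M Sacral 1" = "f6",
              "M Sacral 2" = "f6")
  map_d <- c(upper, visc_d, iliac)
  segments_d <- rbind(g$trunk, chain_t, chain_f, dist_t,
                      branch_stubs(map_d, g$r_branch, g$l_branch))
  outlets_d <- data.frame(name = names(map_d),
                          node = paste0("b_", gsub(" ", "_", names(map_d))),
                          stringsAsFactors = FALSE)
  stations <- data.frame(station = 1:6,
                         tl_node = paste0("t", 1:6),
                         fl_node = paste0("f", 1:6),
                         tl_element = paste0("t_seg_", 1:6),
                         fl_element = paste0("f_seg_", 1:6),
                         stringsAsFactors = FALSE)
  tear <- function(name, from, to, area, role)
    data.frame(name = name, from = from, to = to, area = area,
               channel_length = g$septum, role = role,
               stringsAsFactors = FALSE)
  primary <- rbind(tear("entry", "n_prox", "f0", g$area_entry, "entry"),
                   tear("exit", "t6", "f6", g$area_exit, "exit"))
  # 15 secondary tears, mostly in the visceral region
  sec_station <- c(rep(3, 3), rep(4, 6), rep(5, 4), rep(6, 2))
  secondary <- tear(paste0("sec_", seq_along(sec_station)),
                    paste0("t", sec_station), paste0("f", sec_station),
                    g$area_secondary, "secondary")
  thoracic <- tear(c("thor_1", "thor_2"), c("t1", "t2"), c("f1", "f2"),
                   g$area_secondary, "secondary")

  base_cfg <- list(variant = "dissected_baseline", segments = segments_d,
                   tears = rbind(primary, secondary), outlets = outlets_d,
                   inlet = "n_inlet", stations = stations)
  maximal <- base_cfg
  maximal$variant <- "maximal_tears"
  maximal$tears <- rbind(primary, secondary, thoracic)
  minimal <- base_cfg
  minimal$variant <- "minimal_tears"
  minimal$tears <- primary

  list(undissected = undissected,
       dissected_baseline = base_cfg,
       maximal_tears = maximal,
       minimal_tears = minimal)
}
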