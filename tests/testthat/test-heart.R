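hp <- load_table5_heart("dissected")

test_that("packaged heart parameter sets match their table", {
  expect_equal(hp$period, 1.3)
  expect_equal(hp$E_max, 0.460)
  expect_equal(hp$E_min, 4.102e-3)
  expect_equal(hp$t_max, 0.410)
  expect_equal(hp$P_LA, 533.320)
  hu <- load_table5_heart("undissected")
  expect_equal(hu$E_max, 0.400)
  expect_equal(hu$t_max, 0.420)
  expect_equal(hu$t_relax, 0.210)
})

test_that("elastance is a bounded C0 piecewise-cosine activation", {
  expect_equal(elastance(0, hp), hp$E_min)
  expect_equal(elastance(hp$t_max, hp), hp$E_max)
  expect_equal(elastance(hp$t_max + hp$t_relax, hp), hp$E_min,
               tolerance = 1e-12)
  # half-rise value is the midpoint of the range
  expect_equal(elastance(hp$t_max / 2, hp), (0.460 + 4.102e-3) / 2,
               tolerance = 1e-12)
  tt <- seq(0, 2 * hp$period, by = 1e-3)
  E <- elastance(tt, hp)
  expect_true(all(E >= hp$E_min - 1e-15 & E <= hp$E_max + 1e-15))
  expect_equal(elastance(tt, hp), elastance(tt + hp$period, hp))
  # continuity at the knots
  eps <- 1e-9
  expect_equal(elastance(hp$t_max - eps, hp), elastance(hp$t_max + eps, hp),
               tolerance = 1e-6)
})

test_that("ventricular pressure follows the elastance relation", {
  # diastolic equilibrium: E_min * V_ed equals the atrial preload
  expect_equal(lv_pressure(130000, 0, hp), 533.320, tolerance = 2e-4)
  p_es <- lv_pressure(36000, hp$t_max, hp)
  expect_equal(p_es, 16560)
  expect_equal(canonical_to_mmhg(p_es), 124.2, tolerance = 1e-3)
  expect_error(lv_pressure(hp$V_u, 0, hp), "unstressed")
})

test_that("viscous loss is k*P*Q, linear in flow", {
  expect_equal(viscous_loss(16000, 0, 5e-7), 0)
  expect_equal(viscous_loss(16000, 300000, 5e-7), 2400)
  expect_equal(canonical_to_mmhg(2400), 18, tolerance = 2e-3)
  expect_equal(viscous_loss(16000, 600000, 5e-7),
               2 * viscous_loss(16000, 300000, 5e-7))
  expect_error(viscous_loss(16000, -1, 5e-7), "non-negative")
})

test_that("diode logic fills against preload and precludes back flow", {
  # empty-ish ventricle, low elastance, closed aortic valve: filling
  st <- list(V = 40000, Q_av = 0, Q_mv = 0, av_open = FALSE, mv_open = FALSE)
  st2 <- heart_step(st, t = 0.7, dt = 1e-3, hp, downstream = 12000)
  expect_gt(st2$V, st$V)
  expect_gt(st2$Q_mv, 0)
  expect_identical(st2$Q_av, 0)
  # adverse aortic gradient with zero flow: flow stays exactly zero
  st3 <- list(V = 50000, Q_av = 0, Q_mv = 0, av_open = FALSE, mv_open = FALSE)
  st4 <- heart_step(st3, t = 0.65, dt = 1e-3, hp, downstream = 15000)
  expect_identical(st4$Q_av, 0)
})

test_that("a converged cycle lands in the physiological envelope", {
  sol <- reference_heart_solution()
  expect_gte(sol$stroke_volume, 60000)
  expect_lte(sol$stroke_volume, 130000)
  expect_gte(canonical_to_mmhg(max(sol$P_LV)), 90)
  expect_lte(canonical_to_mmhg(max(sol$P_LV)), 180)
  # no back flow through either valve, ever
  expect_gte(min(sol$Q_av), 0)
  expect_gte(min(sol$Q_mv), 0)
  # volume periodicity at convergence
  expect_lt(abs(sol$V[1] - sol$V[length(sol$V)]),
            0.005 * sol$stroke_volume)
  # end-diastolic volume pinned at the diastolic equilibrium P_LA / E_min
  expect_equal(max(sol$V), hp$P_LA / hp$E_min, tolerance = 1e-3)
})

test_that("PV loop closes, spans the stroke volume and has isovolumetric limbs", {
  sol <- reference_heart_solution()
  loop <- pv_loop(sol)
  expect_equal(max(loop$V) - min(loop$V), sol$stroke_volume,
               tolerance = 0.01)
  # phases with both valves closed hold the volume fixed; exactly two of
  # them (isovolumetric contraction and relaxation) traverse pressure,
  # while late-diastolic diastasis sits at a point of the loop
  closed <- sol$Q_av == 0 & sol$Q_mv == 0
  n <- length(closed)
  shift <- which(!closed)[1]                     # rotate to start on open
  closed_r <- closed[((seq_len(n) + shift - 2L) %% n) + 1L]
  runs <- rle(closed_r)
  ends <- cumsum(runs$lengths)
  p_range <- max(sol$P_LV) - min(sol$P_LV)
  vertical <- 0L
  for (k in which(runs$values & runs$lengths >= 5)) {
    idx <- ((ends[k] - runs$lengths[k]):(ends[k] - 1L) + shift - 1L) %% n + 1L
    expect_lt(abs(diff(range(sol$V[idx]))), 0.02 * sol$stroke_volume)
    if (diff(range(sol$P_LV[idx])) > 0.2 * p_range)
      vertical <- vertical + 1L
  }
  expect_identical(vertical, 2L)
  # degenerate isochoric loop has zero enclosed area
  iso <- pv_loop(rep(1000, 10) + 0, seq(0, 9))
  expect_equal(stroke_work(iso)$work, 0)
  # non-periodic volume trace is rejected
  expect_error(pv_loop(seq(1, 2, length.out = 50) * 1e4, rep(1, 50)),
               "not cyclically converged")
})

test_that("stroke work is the shoelace area, reported in joules", {
  V <- c(36000, 130000, 130000, 36000)
  P <- c(13332 + 500, 13332 + 500, 500, 500)
  w <- stroke_work(structure(list(V = V, P = P), class = "pv_loop"))
  expect_equal(w$work, 94000 * 13332)
  expect_equal(w$work_J, 1.2532, tolerance = 1e-4)
  # orientation-independent
  w2 <- stroke_work(structure(list(V = rev(V), P = rev(P)),
                              class = "pv_loop"))
  expect_equal(w2$work, w$work)
  expect_equal(stroke_work_change(1.0, 1.137), 13.7)
})

test_that("cycle energy bookkeeping closes", {
  sol <- reference_heart_solution()
  p <- sol$params
  dt <- sol$dt
  W <- stroke_work(pv_loop(sol))$work
  supplied <- sum(sol$P_ao * sol$Q_av) * dt +
    p$R_av * sum(sol$Q_av^2) * dt +
    p$k_LV * sum(sol$P_LV * sol$Q_av^2) * dt -
    p$P_LA * sum(sol$Q_mv) * dt +
    p$R_mv * sum(sol$Q_mv^2) * dt
  # within 2% without the inductive term ...
  expect_equal(supplied / W, 1, tolerance = 0.02)
  # ... and to discretisation accuracy once the kinetic energy the
  # instant-closing diodes discard at each closure is included
  dQa <- diff(c(sol$Q_av[length(sol$Q_av)], sol$Q_av))
  dQm <- diff(c(sol$Q_mv[length(sol$Q_mv)], sol$Q_mv))
  inductive <- p$L_av * sum(dQa * sol$Q_av) + p$L_mv * sum(dQm * sol$Q_mv)
  expect_equal((supplied + inductive) / W, 1, tolerance = 2e-3)
})
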