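test_that("effective diameter reproduces the printed tear sizes", {
  expect_equal(round(effective_diameter(135)), 13)
  expect_equal(round(effective_diameter(68), 1), 9.3)
  expect_equal(effective_diameter(pi), 2)
  expect_error(effective_diameter(0), "positive")
})

test_that("Poiseuille resistance has the right value and scalings", {
  blood <- blood_properties()
  expect_equal(poiseuille_resistance(1, 1, blood), 8 * 4e-3 / pi,
               tolerance = 1e-12)
  expect_equal(poiseuille_resistance(1, 1, blood), 1.0186e-2,
               tolerance = 1e-4)
  expect_equal(poiseuille_resistance(2, 1, blood),
               poiseuille_resistance(1, 1, blood) / 16)
  # resistance vanishes with length
  expect_lt(poiseuille_resistance(1, 1e-9, blood), 1e-10)
  expect_error(poiseuille_resistance(-1, 1, blood), "positive")
})

test_that("tear resistance follows the effective-diameter channel model", {
  blood <- blood_properties()
  expect_equal(tear_resistance(135, 2, blood), 1.104e-5, tolerance = 1e-3)
  # R ~ 1/area^2: halving the area quadruples the resistance
  expect_equal(tear_resistance(67.5, 2, blood),
               4 * tear_resistance(135, 2, blood), tolerance = 1e-12)
  expect_gt(tear_resistance(68, 2, blood), tear_resistance(135, 2, blood))
})

test_that("fixture variants build with the expected tear counts", {
  cfgs <- fixture_configs()
  topo <- lapply(cfgs, build_network)
  expect_equal(n_tears(topo$undissected), 0L)
  expect_equal(n_tears(topo$dissected_baseline), 17L)
  expect_equal(n_tears(topo$maximal_tears), 19L)
  expect_equal(n_tears(topo$minimal_tears), 2L)
  # all carry the full 18-outlet registry
  for (tp in topo) expect_equal(nrow(tp$outlets), 18L)
  # entry and exit tear areas in every dissected fixture
  for (nm in c("dissected_baseline", "maximal_tears", "minimal_tears")) {
    tears <- cfgs[[nm]]$tears
    expect_equal(tears$area[tears$name == "entry"], 135)
    expect_equal(tears$area[tears$name == "exit"], 68)
  }
})

test_that("malformed configurations are rejected with the offending element", {
  cfg <- fixture_configs()$dissected_baseline
  bad <- cfg
  bad$outlets$name[1] <- "NotAVessel"
  expect_error(build_network(bad), "NotAVessel")
  bad <- cfg
  bad$segments <- bad$segments[bad$segments$name != "asc", ]
  expect_error(build_network(bad), "disconnected")
  bad <- cfg
  bad$tears$to[bad$tears$name == "entry"] <- "t3"   # both ends true lumen
  expect_error(build_network(bad), "entry.*true-lumen")
})

test_that("a single Windkessel outlet under constant inflow reaches its steady state", {
  topo <- build_network(tiny_config(), registry = tiny_registry())
  Q <- 5000
  sol <- simulate_network(topo, constant_waveform(Q))
  wk <- tiny_registry()$only
  p_expected <- Q * (wk$Rp + wk$Rd) + wk$Pd
  expect_equal(mean(sol$pressures[, match("n1", sol$nodes)]), p_expected,
               tolerance = 1e-6)
})

test_that("identical parallel branches split the flow exactly 50/50", {
  cfg <- list(
    variant = "parallel",
    segments = data.frame(
      name = c("a", "b"), from = "n_in", to = c("na", "nb"),
      radius = 5, length = 50, lumen = "trunk"),
    outlets = data.frame(name = c("x", "x2"), node = c("na", "nb")),
    inlet = "n_in")
  reg <- list(x = windkessel_params(0.1, 2, 1.9),
              x2 = windkessel_params(0.1, 2, 1.9))
  sol <- simulate_network(build_network(cfg, registry = reg),
                          default_inflow())
  q <- colMeans(sol$flows)
  expect_equal(q[[1]], q[[2]], tolerance = 1e-9)
  expect_equal(sol$outlet_summary$mean_flow[1],
               sol$outlet_summary$mean_flow[2], tolerance = 1e-9)
})

test_that("pure-resistor networks agree with a direct linear solve to 1e-10", {
  # independent oracle: assemble and solve the nodal conductance system
  # by hand for the tiny two-branch network under constant inflow
  Q <- 4000
  R1 <- poiseuille_resistance(5, 50)
  wk <- windkessel_params(0.1, 2, 1.9)
  cfg <- list(
    variant = "oracle",
    segments = data.frame(
      name = c("a", "b"), from = "n_in", to = c("na", "nb"),
      radius = 5, length = 50, lumen = "trunk"),
    outlets = data.frame(name = c("x", "x2"), node = c("na", "nb")),
    inlet = "n_in")
  reg <- list(x = wk, x2 = wk)
  sol <- simulate_network(build_network(cfg, registry = reg),
                          constant_waveform(Q))
  g1 <- 1 / R1
  gw <- 1 / (wk$Rp + wk$Rd)
  A <- rbind(c(2 * g1, -g1, -g1),
             c(-g1, g1 + gw, 0),
             c(-g1, 0, g1 + gw))
  b <- c(Q, gw * wk$Pd, gw * wk$Pd)
  p_ref <- solve(A, b)   # n_in, na, nb
  p_sim <- colMeans(sol$pressures)[match(c("n_in", "na", "nb"), sol$nodes)]
  expect_equal(unname(p_sim), unname(p_ref), tolerance = 1e-10)
})

test_that("all fixtures conserve mass and converge within 7 cycles", {
  for (variant in c("undissected", "dissected_baseline",
                    "maximal_tears", "minimal_tears")) {
    sol <- fixture_solution(variant)
    expect_lte(sol$cycles, 7L)
    expect_lt(mass_conservation(sol)$rel_error, 1e-3)
    # instantaneous conservation: summed outlet flow tracks the inflow
    inst <- rowSums(sol$outlet_flows) - sol$inflow
    expect_lt(max(abs(inst)) / mean(sol$inflow), 0.01)
  }
})

test_that("halving the time step leaves outlet cycle means unchanged to 0.5%", {
  s1 <- fixture_solution("dissected_baseline")
  s2 <- simulate_network(build_network(fixture_configs()$dissected_baseline),
                         default_inflow(), dt = 5e-4)
  rel <- abs(s2$outlet_summary$mean_pressure - s1$outlet_summary$mean_pressure) /
    s1$outlet_summary$mean_pressure
  expect_lt(max(rel), 5e-3)
})

test_that("the baseline thoracic flow split is false-lumen dominant", {
  sol <- fixture_solution("dissected_baseline")
  for (s in 1:3) {
    sp <- lumen_flow_split(sol, s)
    expect_equal(sp$fraction_TL + sp$fraction_FL, 100, tolerance = 1e-9)
    expect_gte(sp$fraction_TL, 20)
    expect_lte(sp$fraction_TL, 30)
  }
  # descending total lands in the measured 50-56 cm^3/s range
  expect_gt(lumen_flow_split(sol, 1)$total, 50000)
  expect_lt(lumen_flow_split(sol, 1)$total, 56000)
  expect_error(lumen_flow_split(sol, 99), "unknown station")
  expect_error(lumen_flow_split(fixture_solution("undissected"), 1),
               "no matched")
})

test_that("removing secondary tears redirects flow into the true lumen", {
  cfgs <- fixture_configs()
  res <- tear_sensitivity_study(
    cfgs$dissected_baseline,
    list(minimal = cfgs$minimal_tears, maximal = cfgs$maximal_tears),
    default_inflow())
  minimal <- res[res$variant == "minimal", ]
  maximal <- res[res$variant == "maximal", ]
  # directions at the visceral probe: more true-lumen flow, lower true-lumen
  # peak pressure without the secondary tears
  expect_gt(minimal$d_mean_TL, 0)
  expect_gt(minimal$d_peak_TL, 0)
  expect_lt(minimal$d_peak_P_TL, 0)
  # adding two thoracic tears perturbs far less than removing all 15
  for (col in c("d_mean_TL", "d_peak_TL", "d_mean_FL", "d_peak_FL"))
    expect_lt(abs(maximal[[col]]), abs(minimal[[col]]))
  # identity: a variant equal to the base reports zero change
  res0 <- tear_sensitivity_study(cfgs$dissected_baseline,
                                 list(same = cfgs$dissected_baseline),
                                 default_inflow())
  expect_equal(unlist(res0[1, -1]), c(d_mean_TL = 0, d_peak_TL = 0,
                                      d_mean_FL = 0, d_peak_FL = 0,
                                      d_peak_P_TL = 0), tolerance = 1e-9)
})

test_that("tears equalise pressure between the lumina", {
  gap_min <- septal_pressure_gap(fixture_solution("minimal_tears"))
  gap_base <- septal_pressure_gap(fixture_solution("dissected_baseline"))
  gap_max <- septal_pressure_gap(fixture_solution("maximal_tears"))
  # going from 2 to 17 tears collapses the gap at every station
  expect_true(all(gap_base <= gap_min))
  expect_gt(max(canonical_to_mmhg(gap_min)), 5 * max(canonical_to_mmhg(gap_base)))
  # 17 -> 19 tears: weakly decreasing up to the solver's noise floor
  floor_p <- mmhg_to_canonical(0.005)
  expect_true(all(gap_max <= gap_base + floor_p))
})

test_that("heart-driven network simulation converges and conserves mass", {
  sol <- memo("sol_heart_net",
              simulate_network(build_network(
                fixture_configs()$dissected_baseline),
                list(heart = load_table5_heart("dissected"))))
  expect_lte(sol$cycles, 7L)
  expect_lt(mass_conservation(sol)$rel_error, 1e-3)
  sv <- sum(sol$inflow) * sol$dt
  expect_gt(sv, 60000)
  expect_lt(sv, 130000)
  loop <- pv_loop(sol$heart$V, sol$heart$P_LV)
  expect_gt(stroke_work(loop)$work_J, 0.5)
})

test_that("network configurations survive a JSON round trip", {
  cfg <- fixture_configs()$minimal_tears
  path <- withr::local_tempfile(fileext = ".json")
  write_network_config(cfg, path)
  cfg2 <- read_network_config(path)
  topo <- build_network(cfg2)
  expect_equal(n_tears(topo), 2L)
  expect_equal(sort(topo$nodes), sort(build_network(cfg)$nodes))
})
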