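# Shared fixtures for the suite. Expensive network/heart solutions are
# computed once per test run and memoised here.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_inflow <- function() memo("inflow", generate_inflow())

fixture_solution <- function(variant, ...) {
  memo(paste0("sol_", variant),
       simulate_network(build_network(fixture_configs()[[variant]]),
                        default_inflow(), ...))
}

reference_heart_solution <- function() {
  memo("heart_sol",
       simulate_heart(load_table5_heart("dissected"),
                      load_single_rcr_afterload()))
}

tuned_heart <- function(scale = 1) {
  memo(paste0("tuned_", scale), {
    m <- waveform_metrics(default_inflow())
    tune_elastance(m$mean, m$peak, load_single_rcr_afterload(scale),
                   load_table5_heart("dissected"))
  })
}

# a minimal one-outlet network: inlet node, one segment, one Windkessel
tiny_config <- function(Rp = 0.1, C = 2, Rd = 1.9) {
  list(variant = "tiny",
       segments = data.frame(name = "s1", from = "n_in", to = "n1",
                             radius = 10, length = 50, lumen = "trunk"),
       outlets = data.frame(name = "only", node = "n1"),
       inlet = "n_in")
}

tiny_registry <- function(Rp = 0.1, C = 2, Rd = 1.9)
  list(only = windkessel_params(Rp, C, Rd))

constant_waveform <- function(value, period = 1.3, n = 26) {
  tt <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  waveform(tt, rep(value, n), period = period)
}
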