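# Shared fixtures, all built in code.

ts_grid <- function(n, start = "2016-03-28 00:00:00", by_min = 10) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_min * 60
}

# A one-day forcing with fully controllable physics (constant drivers).
flat_forcing <- function(n = 144, par = rep(1, n), ki = rep(0, n),
                         o_sat = rep(10, n), temperature = rep(5, n),
                         zmix = 1, open_fraction = 1, delta_t = 1 / n,
                         do_init = 10) {
  day_forcing(par = par, temperature = temperature, ki = ki, o_sat = o_sat,
              zmix = zmix, open_fraction = open_fraction, delta_t = delta_t,
              do_init = do_init)
}

# A realistic one-day forcing: half-sine PAR, wind-driven gas exchange.
sunny_forcing <- function(n = 144, zmix = 1.48, open_fraction = 1,
                          temperature = 5, wind = 3, do_init = 10) {
  t_h <- (seq_len(n) - 1) * 24 / n
  par <- pmax(0, 400 * sin(pi * (t_h - 6) / 12))
  par[t_h <= 6 | t_h >= 18] <- 0
  build_day_forcing(par = par, temperature = rep(temperature, n),
                    wind = rep(wind, n), zmix = zmix,
                    open_fraction = open_fraction, delta_t = 1 / n,
                    do_init = do_init)
}

# Desk-scale scenario for pipeline-level tests.
small_scenario <- function(seed = 7, ...) {
  scenario_config(n_control = 2, n_treatment = 2,
                  period_lengths_days = c(2, 2, 2), seed = seed, ...)
}

fast_mcmc <- function(seed = 1, iterations = 1500, burn_in = 300, ...) {
  mcmc_config(iterations = iterations, burn_in = burn_in, seed = seed, ...)
}
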