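#' Scenario configuration for the synthetic ice-removal experiment
#'
#' Describes a replicated two-group pond experiment: control ponds losing ice
#' by natural, gradual melt, and treatment ponds whose ice cover is opened in
#' two steps (10% of pond area, then 50%) before complete ice-off, with three
#' analysis periods (p10, p50, ice_free). Dissolved CO2 accumulated under ice
#' relaxes towards atmospheric equilibrium at a rate proportional to the open
#' area; daily whole-ecosystem GPP is positively and linearly coupled to the
#' CO2 concentration. The generator produces the full sensor file set (DO on a
#' 10-minute grid, PAR, temperature, one shared wind record, daily drivers and
#' CO2 samples) plus the generating truth for every pond-day.
#'
#' @param n_control,n_treatment Ponds per group (default 4 + 4).
#' @param period_lengths_days Lengths of the three periods in days
#'   (default 10, 10, 11).
#' @param start_date First experiment day.
#' @param mean_depth Ice-free water-column depth, m (default 1.48).
#' @param delta_t_minutes Sensor interval, minutes (10 => 144 points per day).
#' @param par_peak Clear-sky PAR amplitude near the end of the experiment,
#'   umol m^-2 s^-1 (underwater sensor depth, hence a few hundred).
#' @param par_cloud_sd,par_step_sd Lognormal sd of the daily cloudiness factor
#'   and the per-step multiplicative noise.
#' @param temp_start,temp_end Water temperature trend endpoints, degrees C.
#' @param temp_diel_amplitude Amplitude of the diel temperature cycle, degrees C.
#' @param wind_mean,wind_sd,wind_phi Mean, stationary sd and lag-1
#'   autocorrelation of the AR(1) wind series, m s^-1 (truncated at 0).
#' @param co2_init,co2_init_sd Mean and between-pond sd of the under-ice CO2
#'   starting concentration, umol L^-1.
#' @param co2_atm_equil Atmospheric-equilibrium CO2, umol L^-1.
#' @param co2_exchange_rate Daily relaxation rate towards equilibrium at fully
#'   open water, d^-1 (scaled by the open-area fraction).
#' @param co2_noise_sd Daily additive CO2 noise, umol L^-1.
#' @param ice_thickness_max Ice thickness under full cover, m; thins
#'   proportionally as the pond opens, and `zmix` is the mean depth minus the
#'   ice thickness.
#' @param control_melt_rate Exponential rate of the control ponds' open-area
#'   ramp, which reaches 1 exactly at the start of the ice-free period.
#' @param coupling Named vector `c(alpha, beta)` of the GPP-CO2 coupling:
#'   true GPP = alpha + beta * CO2 + noise, floored at 0.
#' @param gpp_noise_sd Daily GPP noise, g O2 m^-2 d^-1.
#' @param er_mean,er_sd Mean and sd of the daily ER draw (capped at 0),
#'   g O2 m^-2 d^-1.
#' @param noise_sd_do DO observation noise sigma, g O2 m^-3.
#' @param do_init Starting DO concentration, g O2 m^-3.
#' @param seed Integer seed controlling the whole generated experiment.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_control = 4, n_treatment = 4,
                            period_lengths_days = c(10, 10, 11),
                            start_date = as.Date("2016-03-28"),
                            mean_depth = 1.48,
                            delta_t_minutes = 10,
                            par_peak = 600, par_cloud_sd = 0.25,
                            par_step_sd = 0.15,
                            temp_start = 1, temp_end = 8,
                            temp_diel_amplitude = 0.5,
                            wind_mean = 3, wind_sd = 1, wind_phi = 0.7,
                            co2_init = 150, co2_init_sd = 8,
                            co2_atm_equil = 20,
                            co2_exchange_rate = 0.25,
                            co2_noise_sd = 3,
                            ice_thickness_max = 0.5,
                            control_melt_rate = 0.4,
                            coupling = c(alpha = 0.3, beta = 0.02),
                            gpp_noise_sd = 0.5,
                            er_mean = -3.2, er_sd = 0.4,
                            noise_sd_do = 0.05,
                            do_init = 12,
                            seed = 42) {
  stopifnot(n_control > 0, n_treatment > 0,
            length(period_lengths_days) == 3, all(period_lengths_days > 0),
            mean_depth > ice_thickness_max, coupling[["beta"]] >= 0,
            noise_sd_do > 0, co2_exchange_rate > 0)
  structure(
    list(n_control = n_control, n_treatment = n_treatment,
         period_lengths_days = period_lengths_days,
         start_date = as.Date(start_date), mean_depth = mean_depth,
         delta_t_minutes = delta_t_minutes,
         par_peak = par_peak, par_cloud_sd = par_cloud_sd,
         par_step_sd = par_step_sd,
         temp_start = temp_start, temp_end = temp_end,
         temp_diel_amplitude = temp_diel_amplitude,
         wind_mean = wind_mean, wind_sd = wind_sd, wind_phi = wind_phi,
         co2_init = co2_init, co2_init_sd = co2_init_sd,
         co2_atm_equil = co2_atm_equil,
         co2_exchange_rate = co2_exchange_rate, co2_noise_sd = co2_noise_sd,
         ice_thickness_max = ice_thickness_max,
         control_melt_rate = control_melt_rate,
         coupling = coupling, gpp_noise_sd = gpp_noise_sd,
         er_mean = er_mean, er_sd = er_sd,
         noise_sd_do = noise_sd_do, do_init = do_init, seed = seed),
    class = "scenario_config"
  )
}

n_days <- function(config) sum(config$period_lengths_days)

steps_per_day <- function(config) as.integer(1440 / config$delta_t_minutes)

#' Period boundaries of a scenario
#'
#' @param config A [scenario_config()].
#' @return Data frame with columns `period` (`p10`, `p50`, `ice_free`),
#'   `start`, `end` (inclusive dates).
#' @export
scenario_periods <- function(config) {
  len <- config$period_lengths_days
  starts <- config$start_date + c(0, cumsum(len))[1:3]
  data.frame(period = c("p10", "p50", "ice_free"),
             start = starts, end = starts + len - 1)
}

#' Daily open-area schedule for one group
#'
#' Treatment ponds: open fraction 0.10 through period 1, 0.50 through
#' period 2, and 1 in the ice-free period. Control ponds: a smooth monotone
#' exponential ramp reaching 1 exactly at the start of the ice-free period.
#'
#' @param group `"control"` or `"treatment"`.
#' @param config A [scenario_config()].
#' @return Numeric vector of per-day open fractions, length `sum(periods)`.
#' @export
generate_ice_schedule <- function(group, config = scenario_config()) {
  group <- match.arg(group, c("control", "treatment"))
  len <- config$period_lengths_days
  if (group == "treatment") {
    rep(c(0.10, 0.50, 1), times = len)
  } else {
    d <- seq_len(sum(len))
    pmin(1, exp(config$control_melt_rate * (d - (len[1] + len[2] + 1))))
  }
}

# AR(1) wind, truncated at zero, optionally continuing from `init`.
generate_wind <- function(n, config, init = NULL) {
  phi <- config$wind_phi
  innov <- stats::rnorm(n, 0, config$wind_sd * sqrt(1 - phi^2))
  x0 <- if (is.null(init)) stats::rnorm(1, 0, config$wind_sd) else
    init - config$wind_mean
  x <- as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
  pmax(0, config$wind_mean + x)
}

# Deterministic clear-sky half-sine PAR for day `day` (no noise).
par_clear_sky <- function(config, day) {
  m <- steps_per_day(config)
  frac <- day / n_days(config)
  daylength <- 12 + 4 * frac                    # hours, lengthening in spring
  sunrise <- 12 - daylength / 2
  t_h <- (seq_len(m) - 1) * 24 / m
  amp <- config$par_peak * (0.6 + 0.4 * frac)   # seasonal amplitude trend
  p <- amp * sin(pi * (t_h - sunrise) / daylength)
  p[t_h <= sunrise | t_h >= sunrise + daylength] <- 0
  pmax(0, p)
}

#' One day of diel forcing (PAR, temperature, wind)
#'
#' PAR is a truncated half-sine (zero at night) with a seasonally increasing
#' amplitude and daylength, a lognormal daily cloudiness factor and lognormal
#' per-step noise. Temperature follows a slow seasonal trend with a small
#' diel cycle peaking mid-afternoon. Wind is a positive AR(1) process.
#'
#' @param config A [scenario_config()].
#' @param day Day index within the experiment (1-based).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with numeric vectors `par`, `temperature`, `wind`, one value
#'   per model step (144 for the 10-minute grid).
#' @export
generate_diel_forcing <- function(config = scenario_config(), day = 1,
                                  seed = NULL) {
  local_seed(seed, {
    m <- steps_per_day(config)
    cloud <- exp(stats::rnorm(1, -config$par_cloud_sd^2 / 2,
                              config$par_cloud_sd))
    step_noise <- exp(stats::rnorm(m, -config$par_step_sd^2 / 2,
                                   config$par_step_sd))
    par <- par_clear_sky(config, day) * cloud * step_noise
    t_h <- (seq_len(m) - 1) * 24 / m
    frac <- (day - 1 + t_h / 24) / n_days(config)
    temperature <- config$temp_start +
      (config$temp_end - config$temp_start) * frac +
      config$temp_diel_amplitude * sin(2 * pi * (t_h - 10) / 24) +
      stats::rnorm(m, 0, 0.02)
    wind <- generate_wind(m, config)
    list(par = par, temperature = temperature, wind = wind)
  })
}

#' Daily CO2 concentration series under an open-area schedule
#'
#' First-order relaxation towards atmospheric equilibrium with a daily rate
#' proportional to the open-area fraction, plus additive daily noise:
#' under complete ice cover CO2 stays near its under-ice starting value, and
#' once the pond is fully open it decays geometrically towards equilibrium.
#'
#' @param open_fraction Per-day open-area fractions.
#' @param config A [scenario_config()].
#' @param seed Optional integer seed.
#' @param co2_init Starting concentration, umol L^-1 (default from config).
#' @return Numeric vector of daily CO2 concentrations, umol L^-1.
#' @export
generate_co2_series <- function(open_fraction, config = scenario_config(),
                                seed = NULL, co2_init = config$co2_init) {
  local_seed(seed, {
    d <- length(open_fraction)
    eps <- stats::rnorm(d, 0, config$co2_noise_sd)
    co2 <- numeric(d)
    co2[1] <- co2_init
    for (i in seq_len(d - 1)) {
      co2[i + 1] <- config$co2_atm_equil +
        (co2[i] - config$co2_atm_equil) *
          exp(-config$co2_exchange_rate * open_fraction[i]) + eps[i + 1]
    }
    pmax(co2, 0)
  })
}

#' Generate the full synthetic experiment
#'
#' Builds every pond's forcing and observations for the whole experiment:
#' shared wind; per-pond PAR, temperature, daily drivers (zmix, open
#' fraction, ice thickness), daily CO2; true daily GPP (coupled to CO2),
#' ER and sigma; and the noisy DO series produced by the diel oxygen model
#' itself, chained across days. With `out_dir` the file set is also written
#' as the canonical CSV layout plus `truth.csv`.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory to write the CSV file set into.
#' @param gas A [gas_exchange_config()] used for the DO simulation.
#' @return An object of class `pond_experiment`: list with `config`,
#'   `manifest`, `dates`, `periods`, `wind` (shared [sensor_series()]),
#'   `ponds` (per pond: `do`, `par`, `temperature` series, `daily` drivers,
#'   `co2` data frame) and `truth` (per pond-day generating parameters).
#' @export
generate_experiment <- function(config = scenario_config(), out_dir = NULL,
                                gas = gas_exchange_config()) {
  exp <- local_seed(config$seed, generate_experiment_impl(config, gas))
  if (!is.null(out_dir)) write_experiment(exp, out_dir)
  exp
}

generate_experiment_impl <- function(config, gas) {
  d <- n_days(config)
  m <- steps_per_day(config)
  dates <- config$start_date + seq_len(d) - 1
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  grid <- t0 + (seq_len(d * m) - 1) * config$delta_t_minutes * 60
  manifest <- data.frame(
    pond_id = c(sprintf("C%d", seq_len(config$n_control)),
                sprintf("T%d", seq_len(config$n_treatment))),
    group = rep(c("control", "treatment"),
                c(config$n_control, config$n_treatment)),
    stringsAsFactors = FALSE)
  wind_all <- generate_wind(d * m, config)
  wind_series <- sensor_series("wind", grid, wind_all,
                               interval = config$delta_t_minutes)
  ponds <- list()
  truth <- list()
  for (p in seq_len(nrow(manifest))) {
    id <- manifest$pond_id[p]
    grp <- manifest$group[p]
    open <- generate_ice_schedule(grp, config)
    ice <- config$ice_thickness_max * (1 - open)
    zmix <- config$mean_depth - ice
    co2_init_p <- stats::rnorm(1, config$co2_init, config$co2_init_sd)
    co2 <- generate_co2_series(open, config, co2_init = co2_init_p)
    par_all <- numeric(d * m)
    temp_all <- numeric(d * m)
    do_obs <- numeric(d * m)
    gpp_true <- er_true <- do_init_true <- numeric(d)
    do_init <- config$do_init
    for (day in seq_len(d)) {
      i <- (day - 1) * m + seq_len(m)
      cloud <- exp(stats::rnorm(1, -config$par_cloud_sd^2 / 2,
                                config$par_cloud_sd))
      step_noise <- exp(stats::rnorm(m, -config$par_step_sd^2 / 2,
                                     config$par_step_sd))
      par <- par_clear_sky(config, day) * cloud * step_noise
      t_h <- (seq_len(m) - 1) * 24 / m
      frac <- (day - 1 + t_h / 24) / d
      temperature <- config$temp_start +
        (config$temp_end - config$temp_start) * frac +
        config$temp_diel_amplitude * sin(2 * pi * (t_h - 10) / 24) +
        stats::rnorm(m, 0, 0.02)
      gpp <- max(0, config$coupling[["alpha"]] +
                   config$coupling[["beta"]] * co2[day] +
                   stats::rnorm(1, 0, config$gpp_noise_sd))
      er <- min(0, stats::rnorm(1, config$er_mean, config$er_sd))
      forcing <- build_day_forcing(
        par = par, temperature = temperature, wind = wind_all[i],
        zmix = zmix[day], open_fraction = open[day],
        delta_t = config$delta_t_minutes / 1440, do_init = do_init,
        gas = gas)
      clean <- simulate_do(list(gpp = gpp, er = er), forcing)
      do_obs[i] <- clean[seq_len(m)] +
        stats::rnorm(m, 0, config$noise_sd_do)
      par_all[i] <- par
      temp_all[i] <- temperature
      gpp_true[day] <- gpp
      er_true[day] <- er
      do_init_true[day] <- do_init
      do_init <- clean[m + 1]
    }
    ponds[[id]] <- list(
      do = sensor_series("DO", grid, do_obs,
                         interval = config$delta_t_minutes),
      par = sensor_series("PAR", grid, par_all,
                          interval = config$delta_t_minutes),
      temperature = sensor_series("temperature", grid, temp_all,
                                  interval = config$delta_t_minutes),
      daily = data.frame(date = dates, zmix = zmix, open_fraction = open,
                         ice_thickness = ice),
      co2 = data.frame(date = dates, co2 = co2))
    truth[[id]] <- data.frame(
      pond_id = id, group = grp, date = dates,
      gpp = gpp_true, er = er_true, sigma = config$noise_sd_do,
      do_init = do_init_true, co2 = co2, stringsAsFactors = FALSE)
  }
  structure(
    list(config = config, manifest = manifest, dates = dates,
         periods = scenario_periods(config), wind = wind_series,
         ponds = ponds, truth = do.call(rbind, c(truth, make.row.names = FALSE))),
    class = "pond_experiment"
  )
}

#' Assemble one day's forcing from raw drivers
#'
#' Computes the per-step exchange rate Ki (wind -> K600 -> Schmidt-scaled,
#' depth-normalized) and O2 saturation from temperature, and packs them with
#' PAR into a [day_forcing()].
#'
#' @param par,temperature,wind Per-step driver vectors (equal length).
#' @param zmix Mixing depth, m.
#' @param open_fraction Open-area fraction in \[0, 1\].
#' @param delta_t Step in days.
#' @param do_init Initial DO, g m^-3.
#' @param gas A [gas_exchange_config()].
#' @return A [day_forcing()].
#' @export
build_day_forcing <- function(par, temperature, wind, zmix, open_fraction,
                              delta_t = 1 / 144, do_init = NULL,
                              gas = gas_exchange_config()) {
  k600 <- k600_from_wind(wind, gas)
  ki <- k_o2_daily(k600, temperature, zmix, gas)
  o_sat <- o2_saturation(temperature, gas$barometric_pressure, gas$salinity)
  day_forcing(par = par, temperature = temperature, ki = ki, o_sat = o_sat,
              zmix = zmix, open_fraction = open_fraction,
              delta_t = delta_t, do_init = do_init)
}

#' @export
print.pond_experiment <- function(x, ...) {
  cat(sprintf("<pond_experiment> %d ponds (%d control + %d treatment), %d days (%s .. %s)\n",
              nrow(x$manifest), sum(x$manifest$group == "control"),
              sum(x$manifest$group == "treatment"), length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)])))
  invisible(x)
}

#' Write / read the experiment CSV file set
#'
#' The canonical layout: `manifest.csv`, `wind.csv`, per pond
#' `<id>_do.csv`, `<id>_par.csv`, `<id>_temperature.csv`, `<id>_drivers.csv`,
#' plus combined `co2.csv` and `truth.csv`.
#'
#' @param exp A `pond_experiment`.
#' @param dir Directory (created if absent).
#' @return `dir` (write) or a `pond_experiment` (read), invisibly for write.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(exp$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sensor_csv(exp$wind, file.path(dir, "wind.csv"))
  co2 <- list()
  for (id in names(exp$ponds)) {
    pond <- exp$ponds[[id]]
    write_sensor_csv(pond$do, file.path(dir, paste0(id, "_do.csv")))
    write_sensor_csv(pond$par, file.path(dir, paste0(id, "_par.csv")))
    write_sensor_csv(pond$temperature,
                     file.path(dir, paste0(id, "_temperature.csv")))
    drivers <- pond$daily
    drivers$date <- format(drivers$date)
    drivers <- cbind(pond_id = id, drivers)
    utils::write.csv(format(drivers, digits = 10, trim = TRUE, scientific = FALSE),
                     file.path(dir, paste0(id, "_drivers.csv")),
                     row.names = FALSE, quote = FALSE)
    co2[[id]] <- cbind(pond_id = id, pond$co2)
  }
  co2 <- do.call(rbind, c(co2, make.row.names = FALSE))
  co2$date <- format(co2$date)
  co2$co2 <- sprintf("%.10g", co2$co2)
  utils::write.csv(co2, file.path(dir, "co2.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- exp$truth
  truth$date <- format(truth$date)
  for (col in c("gpp", "er", "sigma", "do_init", "co2")) {
    truth[[col]] <- sprintf("%.10g", truth[[col]])
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_experiment
#' @param config The scenario the files were generated from (carried along for
#'   period boundaries and the model grid).
#' @export
load_experiment <- function(dir, config = scenario_config()) {
  manifest <- read_pond_manifest(file.path(dir, "manifest.csv"))
  wind <- read_sensor_csv(file.path(dir, "wind.csv"), "wind",
                          interval = config$delta_t_minutes)
  co2_all <- utils::read.csv(file.path(dir, "co2.csv"),
                             stringsAsFactors = FALSE)
  co2_all$date <- as.Date(co2_all$date)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    tr <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    tr$date <- as.Date(tr$date)
    tr
  } else NULL
  ponds <- list()
  for (p in seq_len(nrow(manifest))) {
    id <- manifest$pond_id[p]
    daily <- read_daily_drivers(file.path(dir, paste0(id, "_drivers.csv")))
    ponds[[id]] <- list(
      do = read_sensor_csv(file.path(dir, paste0(id, "_do.csv")), "DO",
                           interval = config$delta_t_minutes),
      par = read_sensor_csv(file.path(dir, paste0(id, "_par.csv")), "PAR",
                            interval = config$delta_t_minutes),
      temperature = read_sensor_csv(
        file.path(dir, paste0(id, "_temperature.csv")), "temperature",
        interval = config$delta_t_minutes),
      daily = daily[, c("date", "zmix", "open_fraction", "ice_thickness")],
      co2 = co2_all[co2_all$pond_id == id, c("date", "co2")])
  }
  dates <- ponds[[1]]$daily$date
  structure(
    list(config = config, manifest = manifest, dates = dates,
         periods = scenario_periods(config), wind = wind,
         ponds = ponds, truth = truth),
    class = "pond_experiment"
  )
}
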