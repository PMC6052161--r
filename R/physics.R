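#' Gas-exchange configuration
#'
#' Bundles the choices that turn a wind record into a per-step oxygen exchange
#' rate: the K600 wind model, the Schmidt-number exponent used to convert K600
#' to a gas-specific piston velocity, and the ambient conditions entering the
#' oxygen saturation calculation.
#'
#' @param k600_model Wind parameterization of the gas transfer velocity.
#'   `"cole_caraco_1998"` uses k600 = 2.07 + 0.215 * U10^1.7 (cm h^-1);
#'   `"constant"` uses `constant_k600` regardless of wind.
#' @param schmidt_exponent Exponent n in (Sc/600)^n. Must lie in
#'   \[-2/3, -0.5\]; -0.5 is the usual choice for wavy, low-wind lake
#'   surfaces, -2/3 for smooth surfaces.
#' @param constant_k600 Fixed K600 in cm h^-1, used only when
#'   `k600_model = "constant"`.
#' @param barometric_pressure Station pressure in kPa (default one standard
#'   atmosphere, 101.325 kPa).
#' @param salinity Practical salinity (PSU); 0 for fresh water.
#' @return An object of class `gas_exchange_config`.
#' @export
#' @examples
#' cfg <- gas_exchange_config()
#' k600_from_wind(5, cfg)
gas_exchange_config <- function(k600_model = c("cole_caraco_1998", "constant"),
                                schmidt_exponent = -0.5,
                                constant_k600 = NULL,
                                barometric_pressure = 101.325,
                                salinity = 0) {
  k600_model <- match.arg(k600_model)
  if (!is.numeric(schmidt_exponent) || length(schmidt_exponent) != 1 ||
      schmidt_exponent < -2 / 3 - 1e-9 || schmidt_exponent > -0.5 + 1e-9) {
    stop("`schmidt_exponent` must be a single value in [-2/3, -0.5]",
         call. = FALSE)
  }
  if (k600_model == "constant") {
    if (is.null(constant_k600) || !is.numeric(constant_k600) ||
        constant_k600 < 0) {
      stop("`constant_k600` must be a non-negative number when ",
           "k600_model = \"constant\"", call. = FALSE)
    }
  }
  if (barometric_pressure <= 0) {
    stop("`barometric_pressure` must be positive (kPa)", call. = FALSE)
  }
  if (salinity < 0) stop("`salinity` must be non-negative", call. = FALSE)
  structure(
    list(k600_model = k600_model,
         schmidt_exponent = schmidt_exponent,
         constant_k600 = constant_k600,
         barometric_pressure = barometric_pressure,
         salinity = salinity),
    class = "gas_exchange_config"
  )
}

#' Oxygen saturation concentration
#'
#' Equilibrium dissolved-oxygen concentration of water in contact with the
#' atmosphere, from the Benson-Krause formulation (the basis of the USGS
#' solubility tables), with a multiplicative pressure correction and an
#' exponential salinity correction.
#'
#' @param temperature Water temperature in degrees C; must lie in (-2, 40).
#' @param pressure Barometric pressure in kPa.
#' @param salinity Practical salinity (PSU).
#' @return Saturation DO concentration in g O2 m^-3 (equivalently mg L^-1).
#' @export
#' @examples
#' o2_saturation(20)         # about 9.09 g m^-3
#' o2_saturation(0)          # about 14.62 g m^-3
o2_saturation <- function(temperature, pressure = 101.325, salinity = 0) {
  if (any(!is.finite(temperature)) ||
      any(temperature <= -2) || any(temperature >= 40)) {
    stop("`temperature` must lie in (-2, 40) degrees C", call. = FALSE)
  }
  tk <- temperature + 273.15
  # Benson & Krause equilibrium concentration at 1 atm moist air, mg L^-1
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.2438e10 / tk^3 - 8.621949e11 / tk^4
  sal <- exp(-salinity * (0.017674 - 10.754 / tk + 2140.7 / tk^2))
  exp(ln_c) * sal * pressure / 101.325
}

#' Schmidt number of oxygen in fresh water
#'
#' Temperature-dependent Schmidt number Sc = kinematic viscosity / molecular
#' diffusivity for O2 in fresh water (Wanninkhof's freshwater polynomial).
#' Used to rescale K600 to an oxygen-specific piston velocity.
#'
#' @param temperature Water temperature in degrees C; must lie in (0, 30).
#' @return Dimensionless Schmidt number (about 530 at 20 degrees C).
#' @export
schmidt_o2 <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature <= 0) || any(temperature >= 30)) {
    stop("`temperature` must lie in (0, 30) degrees C", call. = FALSE)
  }
  1800.6 - 120.10 * temperature + 3.7818 * temperature^2 -
    0.047608 * temperature^3
}

#' Gas transfer velocity K600 from wind speed
#'
#' Piston velocity normalized to Schmidt number 600, from wind speed at 10 m.
#' The default Cole-Caraco model is k600 = 2.07 + 0.215 * U10^1.7 (cm h^-1).
#'
#' @param u10 Wind speed at 10 m height, m s^-1 (non-negative).
#' @param config A [gas_exchange_config()].
#' @return K600 in cm h^-1, same length as `u10`.
#' @export
k600_from_wind <- function(u10, config = gas_exchange_config()) {
  if (any(!is.finite(u10)) || any(u10 < 0)) {
    stop("`u10` must be non-negative wind speed in m s^-1", call. = FALSE)
  }
  switch(config$k600_model,
    cole_caraco_1998 = 2.07 + 0.215 * u10^1.7,
    constant = rep(config$constant_k600, length(u10))
  )
}

#' Depth-normalized oxygen exchange rate Ki
#'
#' Converts K600 to the oxygen piston velocity via the Schmidt-number ratio,
#' changes units from cm h^-1 to m d^-1, and divides by the mixing depth to
#' give the first-order air-water exchange rate Ki (d^-1) that multiplies the
#' saturation deficit in the diel oxygen model.
#'
#' @param k600 Gas transfer velocity at Sc = 600, cm h^-1.
#' @param temperature Water temperature, degrees C.
#' @param zmix Mixing depth in m (> 0).
#' @param config A [gas_exchange_config()]; supplies the Schmidt exponent.
#' @return Exchange rate Ki in d^-1.
#' @export
#' @examples
#' # 2.07 cm h^-1 is 0.4968 m d^-1; with Sc = 600 and zmix = 1 m, Ki = 0.4968
#' k_o2_daily(2.07, 17.54, zmix = 1)
k_o2_daily <- function(k600, temperature, zmix,
                       config = gas_exchange_config()) {
  if (any(!is.finite(zmix)) || any(zmix <= 0)) {
    stop("`zmix` must be positive (m)", call. = FALSE)
  }
  sc <- schmidt_o2(temperature)
  k_o2 <- k600 * (sc / 600)^config$schmidt_exponent  # cm h^-1
  k_o2 * 24 / 100 / zmix                             # m d^-1 / m -> d^-1
}
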