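#' Daily metabolism parameters
#'
#' The three unknowns of one pond-day fit: gross primary production (GPP) and
#' ecosystem respiration (ER), both areal rates in g O2 m^-2 d^-1, and the
#' observation noise sigma (g O2 m^-3). By convention ER is stored as a
#' non-positive number and *added* in the model. During inference GPP and ER
#' are unconstrained; the sign constraints here apply to simulation inputs.
#'
#' @param gpp Gross primary production, g O2 m^-2 d^-1 (>= 0 for simulation).
#' @param er Ecosystem respiration, g O2 m^-2 d^-1 (<= 0).
#' @param sigma Observation noise standard deviation, g O2 m^-3 (> 0).
#' @return An object of class `metabolism_params`.
#' @export
metabolism_params <- function(gpp, er, sigma = 0.05) {
  if (!is.finite(gpp) || gpp < 0) stop("`gpp` must be >= 0", call. = FALSE)
  if (!is.finite(er) || er > 0) stop("`er` must be <= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(gpp = gpp, er = er, sigma = sigma),
            class = "metabolism_params")
}

#' One day's forcing for the diel oxygen model
#'
#' Per-step drivers on the model grid (n steps of `delta_t` days, 144 for a
#' 10-minute grid), plus the day's scalars. The PAR normalization constant
#' `par_total` is the daily sum of per-step PAR, so that the PAR-apportioned
#' GPP term integrates to GPP/zmix over the day.
#'
#' @param par Per-step PAR, umol m^-2 s^-1 (non-negative).
#' @param temperature Per-step water temperature, degrees C.
#' @param ki Per-step exchange rate Ki, d^-1 (see [k_o2_daily()]).
#' @param o_sat Per-step O2 saturation, g m^-3 (see [o2_saturation()]).
#' @param zmix Mixing depth, m.
#' @param open_fraction Fraction of pond area open to the atmosphere, in
#'   \[0, 1\]; scales the exchange term (0 = sealed by ice).
#' @param delta_t Time step in days (10 min = 1/144).
#' @param do_init Initial DO, g m^-3 (the day's first observation when fitting).
#' @param par_total Daily PAR sum; defaults to `sum(par)` and must match it to
#'   1e-9 relative tolerance.
#' @return An object of class `day_forcing`.
#' @export
day_forcing <- function(par, temperature, ki, o_sat, zmix, open_fraction,
                        delta_t = 1 / 144, do_init = NULL,
                        par_total = sum(par)) {
  n <- length(par)
  if (n == 0) stop("empty forcing", call. = FALSE)
  lens <- c(length(temperature), length(ki), length(o_sat))
  if (any(lens != n)) {
    stop("per-step vectors must have equal length", call. = FALSE)
  }
  if (any(par < 0)) stop("PAR must be non-negative", call. = FALSE)
  if (any(ki < 0)) stop("ki must be non-negative", call. = FALSE)
  if (!is.finite(zmix) || zmix <= 0) stop("zmix must be > 0", call. = FALSE)
  if (open_fraction < 0 || open_fraction > 1) {
    stop("open_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (delta_t <= 0) stop("delta_t must be > 0", call. = FALSE)
  s <- sum(par)
  if (abs(par_total - s) > 1e-9 * max(1, abs(s))) {
    stop("par_total must equal sum(par) to 1e-9 relative tolerance",
         call. = FALSE)
  }
  if (is.null(do_init)) do_init <- 10
  structure(
    list(par = par, par_total = par_total, temperature = temperature,
         ki = ki, o_sat = o_sat, zmix = zmix,
         open_fraction = open_fraction, delta_t = delta_t,
         do_init = do_init, n = n),
    class = "day_forcing"
  )
}

#' PAR weights apportioning daily GPP to model steps
#'
#' Each step receives the fraction PAR_i / sum(PAR) of the day's GPP, so the
#' weights sum to 1 on any day with light. On an all-dark day (all PAR zero)
#' the weights are all zero and no GPP enters the model.
#'
#' @param par Per-step PAR values (non-negative).
#' @param par_total Normalization constant, defaulting to `sum(par)`.
#' @return Numeric vector of fractions, same length as `par`.
#' @export
par_weights <- function(par, par_total = sum(par)) {
  if (any(par < 0)) stop("PAR must be non-negative", call. = FALSE)
  if (par_total <= 0) return(rep(0, length(par)))
  par / par_total
}

#' Simulate the diel dissolved-oxygen curve
#'
#' Steps the modeled DO concentration through one day:
#' \deqn{mO_i = mO_{i-1} + \frac{GPP}{zmix}\frac{PAR_i}{\sum PAR}
#'   + \frac{ER}{zmix}\Delta t
#'   + f\, K_i (O_{sat,i} - mO_{i-1})\Delta t}
#' where f is the open-area fraction scaling the air-water exchange term
#' (f = 0 under complete ice cover, so metabolism accumulates with no
#' exchange). The update is the explicit recursion above; it requires the
#' per-step stability condition Ki * delta_t < 1.
#'
#' @param params A [metabolism_params()] (sigma is ignored here).
#' @param forcing A [day_forcing()].
#' @return Numeric vector of length `n + 1`: `mO[1]` is `do_init` and
#'   `mO[i+1]` the state after step i.
#' @export
#' @examples
#' f <- day_forcing(par = rep(1, 144), temperature = rep(10, 144),
#'                  ki = rep(0, 144), o_sat = rep(11, 144),
#'                  zmix = 1, open_fraction = 0, do_init = 10)
#' do <- simulate_do(metabolism_params(2, 0), f)
#' do[145] - do[1]  # = GPP / zmix = 2
simulate_do <- function(params, forcing) {
  stopifnot(inherits(forcing, "day_forcing"))
  gpp <- params$gpp
  er <- params$er
  dt <- forcing$delta_t
  if (any(forcing$ki * dt >= 1)) {
    stop("unstable step: Ki * delta_t >= 1; use a smaller delta_t",
         call. = FALSE)
  }
  w <- par_weights(forcing$par, forcing$par_total)
  f <- forcing$open_fraction
  a <- 1 - f * forcing$ki * dt
  b <- gpp / forcing$zmix * w + er / forcing$zmix * dt +
    f * forcing$ki * forcing$o_sat * dt
  n <- forcing$n
  mo <- numeric(n + 1)
  mo[1] <- forcing$do_init
  if (min(a) > 0.5) {
    # solve the affine recursion in closed form (numerically safe: a ~ 1)
    cp <- cumprod(a)
    mo[-1] <- cp * (forcing$do_init + cumsum(b / cp))
  } else {
    for (i in seq_len(n)) mo[i + 1] <- a[i] * mo[i] + b[i]
  }
  mo
}

#' Simulate a noisy ("observed") dissolved-oxygen series
#'
#' The deterministic [simulate_do()] trajectory plus independent Gaussian
#' observation noise with standard deviation `params$sigma`, reproducibly
#' seeded. The caller's RNG state is left untouched.
#'
#' @inheritParams simulate_do
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG stream.
#' @return Numeric vector of length `n + 1`.
#' @export
simulate_do_noisy <- function(params, forcing, seed = NULL) {
  if (params$sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  clean <- simulate_do(params, forcing)
  noise <- local_seed(seed, stats::rnorm(length(clean), 0, params$sigma))
  clean + noise
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
# With seed = NULL the global stream is used (and advanced) as usual.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
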