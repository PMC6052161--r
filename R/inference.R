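#' Prior configuration for the metabolism fit
#'
#' Weakly informative priors: GPP ~ Normal(gpp_mean, gpp_sd), ER ~
#' Normal(er_mean, er_sd), both unbounded (negative-GPP days are removed
#' after fitting, not prevented during sampling), and sigma ~ half-Normal
#' with scale `sigma_sd` on (0, Inf).
#'
#' @param gpp_mean,gpp_sd Prior mean / sd for GPP (g O2 m^-2 d^-1).
#' @param er_mean,er_sd Prior mean / sd for ER (g O2 m^-2 d^-1).
#' @param sigma_sd Half-normal scale for the observation noise (g O2 m^-3).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(gpp_mean = 3, gpp_sd = 10,
                         er_mean = -5, er_sd = 10,
                         sigma_sd = 1) {
  stopifnot(gpp_sd > 0, er_sd > 0, sigma_sd > 0)
  structure(list(gpp_mean = gpp_mean, gpp_sd = gpp_sd,
                 er_mean = er_mean, er_sd = er_sd, sigma_sd = sigma_sd),
            class = "prior_config")
}

log_prior <- function(gpp, er, sigma, priors) {
  if (sigma <= 0) return(-Inf)
  stats::dnorm(gpp, priors$gpp_mean, priors$gpp_sd, log = TRUE) +
    stats::dnorm(er, priors$er_mean, priors$er_sd, log = TRUE) +
    log(2) + stats::dnorm(sigma, 0, priors$sigma_sd, log = TRUE)
}

#' Gaussian log-likelihood of an observed DO series
#'
#' Independent Gaussian observation error: the sum of log-densities of
#' `observed - simulate_do(params, forcing)` with standard deviation
#' `params$sigma`. The modeled series is compared at the observation times
#' (the first `n` model states, the first being the anchored `do_init`).
#'
#' @param params A [metabolism_params()] or list with `gpp`, `er`, `sigma`.
#' @param forcing A [day_forcing()].
#' @param observed Numeric DO observations, length `forcing$n`.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(params, forcing, observed) {
  if (params$sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (length(observed) != forcing$n) {
    stop("`observed` must match the forcing grid (", forcing$n, " points)",
         call. = FALSE)
  }
  mod <- simulate_do(params, forcing)[seq_len(forcing$n)]
  sum(stats::dnorm(observed, mod, params$sigma, log = TRUE))
}

#' Log posterior density of the metabolism parameters
#'
#' `log_likelihood()` plus the log prior density. Outside the prior support
#' (sigma <= 0) the value is `-Inf`, which a Metropolis sampler rejects;
#' no error is thrown.
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_config()].
#' @return The unnormalized log posterior (scalar, possibly `-Inf`).
#' @export
log_posterior <- function(params, forcing, observed,
                          priors = prior_config()) {
  if (params$sigma <= 0) return(-Inf)
  log_likelihood(params, forcing, observed) +
    log_prior(params$gpp, params$er, params$sigma, priors)
}

#' MCMC configuration
#'
#' @param iterations Total chain length (default 10000).
#' @param burn_in Initial iterations discarded before summarizing (default
#'   1000); must be smaller than `iterations`.
#' @param proposal_sd Per-parameter Gaussian proposal standard deviations.
#' @param seed Integer seed for the sampler (`NULL` = current RNG stream).
#' @param init Named starting values.
#' @param tune If `TRUE`, a pre-run tuning phase rescales `proposal_sd` by a
#'   common factor towards a 20-45% acceptance rate; tuning draws are
#'   discarded and never count toward `iterations`.
#' @param tune_blocks,tune_block_size Maximum number and size of tuning blocks.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 10000, burn_in = 1000,
                        proposal_sd = c(gpp = 0.2, er = 0.2, sigma = 0.01),
                        seed = NULL,
                        init = c(gpp = 3, er = -5, sigma = 0.1),
                        tune = TRUE, tune_blocks = 15, tune_block_size = 100) {
  if (!(iterations > burn_in) || burn_in < 0) {
    stop("need iterations > burn_in >= 0", call. = FALSE)
  }
  if (any(proposal_sd <= 0)) stop("proposal_sd must be > 0", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd, seed = seed, init = init,
                 tune = isTRUE(tune), tune_blocks = tune_blocks,
                 tune_block_size = tune_block_size),
            class = "mcmc_config")
}

#' Random-walk Metropolis sampler
#'
#' Block updates with symmetric Gaussian proposals, one scale per parameter;
#' a proposal is accepted with probability min(1, exp(change in log target)).
#' With `tune = TRUE` a discarded pre-run phase adapts the proposal towards a
#' 20-45% acceptance rate, learning the chain's local covariance so the frozen
#' proposal follows any parameter correlations; without tuning the proposal is
#' diagonal with scales `proposal_sd`. With a fixed seed the chain is
#' bit-reproducible. The returned chain holds all `iterations` rows (burn-in
#' included); rejected proposals appear as duplicated consecutive rows.
#'
#' @param config An [mcmc_config()]; `init` and `proposal_sd` must have the
#'   same length (any number of parameters).
#' @param target Function mapping a named numeric parameter vector to the log
#'   target density (may return `-Inf`).
#' @return An object of class `mcmc_chain`: list with `samples` (iterations x
#'   parameters matrix), `log_posterior` (per-iteration values),
#'   `acceptance_rate`, and the proposal scales actually used.
#' @export
metropolis_sample <- function(config, target) {
  init <- config$init
  sd0 <- config$proposal_sd
  if (length(init) != length(sd0)) {
    stop("init and proposal_sd must have the same length", call. = FALSE)
  }
  run <- function() {
    cur <- init
    lp <- target(cur)
    if (!is.finite(lp)) {
      stop("initialization error: log target is not finite at init",
           call. = FALSE)
    }
    npar <- length(cur)
    prop_chol <- diag(sd0, npar)  # proposal = cur + rnorm %*% prop_chol
    if (config$tune) {
      in_window <- 0L
      for (b in seq_len(config$tune_blocks)) {
        acc <- 0L
        block <- matrix(NA_real_, config$tune_block_size, npar)
        for (i in seq_len(config$tune_block_size)) {
          prop <- cur + drop(stats::rnorm(npar) %*% prop_chol)
          lpp <- target(prop)
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
            cur <- prop; lp <- lpp; acc <- acc + 1L
          }
          block[i, ] <- cur
        }
        rate <- acc / config$tune_block_size
        if (rate >= 0.2 && rate <= 0.45) {
          # demand two consecutive in-window blocks after a minimum of five,
          # so scales frozen during the initial transient do not stick
          in_window <- in_window + 1L
          if (b >= 5 && in_window >= 2) break
          next
        }
        in_window <- 0L
        adapted <- FALSE
        if (rate >= 0.1) {
          # reshape the proposal to the chain's local covariance
          # (2.4/sqrt(d) is the classic random-walk scaling)
          cv <- stats::cov(block)
          ch <- tryCatch(chol(cv + diag(1e-12, npar)), error = function(e) NULL)
          if (!is.null(ch)) {
            prop_chol <- ch * 2.4 / sqrt(npar)
            adapted <- TRUE
          }
        }
        if (!adapted) {
          # too few acceptances to learn the shape: move all scales together
          prop_chol <- prop_chol * exp(2 * (max(rate, 0.01) - 0.3))
        }
      }
    }
    n <- config$iterations
    samples <- matrix(NA_real_, n, npar,
                      dimnames = list(NULL, names(init)))
    lps <- numeric(n)
    accepted <- 0L
    for (i in seq_len(n)) {
      prop <- cur + drop(stats::rnorm(npar) %*% prop_chol)
      lpp <- target(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        cur <- prop; lp <- lpp; accepted <- accepted + 1L
      }
      samples[i, ] <- cur
      lps[i] <- lp
    }
    structure(list(samples = samples, log_posterior = lps,
                   acceptance_rate = accepted / n,
                   proposal_sd = sqrt(colSums(prop_chol^2))),
              class = "mcmc_chain")
  }
  local_seed(config$seed, run())
}

# Split R-hat: compare the two halves of a (post-burn-in) chain segment.
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  h1 <- x[seq_len(n)]
  h2 <- x[seq_len(n) + n]
  w <- (stats::var(h1) + stats::var(h2)) / 2
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- n * stats::var(c(mean(h1), mean(h2)))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Posterior summaries and convergence diagnostics of a chain
#'
#' Drops the first `burn_in` rows, then reports the median and central 95%
#' credible interval of each parameter plus its split R-hat (the two halves of
#' the retained chain compared; pass threshold <= 1.05). A degenerate
#' (zero-variance) parameter has an undefined R-hat and is flagged as not
#' converged rather than raising an error.
#'
#' @param chain An `mcmc_chain` from [metropolis_sample()] (or a numeric
#'   matrix of samples).
#' @param burn_in Number of initial rows to discard.
#' @return A data frame with one row per parameter (`parameter`, `median`,
#'   `lower`, `upper`, `rhat`) and attribute `converged` (all finite R-hats
#'   <= 1.05).
#' @export
summarize_chain <- function(chain, burn_in = 0) {
  samples <- if (inherits(chain, "mcmc_chain")) chain$samples else chain
  samples <- as.matrix(samples)
  if (burn_in >= nrow(samples)) {
    stop("burn_in must be smaller than the chain length", call. = FALSE)
  }
  kept <- samples[(burn_in + 1):nrow(samples), , drop = FALSE]
  q <- apply(kept, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  rhat <- apply(kept, 2, split_rhat)
  out <- data.frame(parameter = colnames(kept) %||% paste0("p", seq_len(ncol(kept))),
                    median = q[2, ], lower = q[1, ], upper = q[3, ],
                    rhat = rhat, row.names = NULL)
  attr(out, "converged") <- all(is.finite(rhat) & rhat <= 1.05)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quality-control configuration for day fits
#'
#' @param r2_min Minimum r-squared (squared Pearson correlation between
#'   measured and modeled DO at the posterior median) for a day to be kept;
#'   the boundary value itself is kept.
#' @param rmse_max Maximum RMSE (g O2 m^-3); the boundary value is kept.
#' @param rhat_max Convergence threshold for split R-hat.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(r2_min = 0.5, rmse_max = 0.5, rhat_max = 1.05) {
  structure(list(r2_min = r2_min, rmse_max = rmse_max, rhat_max = rhat_max),
            class = "qc_config")
}

#' Fit one pond-day by MCMC
#'
#' Runs the random-walk Metropolis sampler on the log posterior of (GPP, ER,
#' sigma) given one day's forcing and DO observations, then summarizes the
#' chain and applies the day-level quality filters. The fit quality (RMSE and
#' r-squared between measured and modeled DO) is evaluated at the posterior
#' medians.
#'
#' The day's initial DO is sampled as a fourth, nuisance parameter with a flat
#' prior, initialized at the first observation and informed by it through the
#' likelihood. Fixing it to the first observation instead would treat that
#' (noisy) reading as exact and push its error into GPP and ER, leaving the
#' posterior intervals far too narrow; sampling it keeps the observation model
#' coherent and the intervals calibrated.
#'
#' The forward model is linear in (GPP, ER, initial DO) for fixed forcing, so
#' the sampler evaluates the Gaussian likelihood through precomputed
#' sufficient statistics of that linear decomposition; results are identical
#' (to floating-point round-off) to calling [log_posterior()] directly.
#'
#' @param forcing A [day_forcing()].
#' @param observed DO observations, length `forcing$n`; the first one is the
#'   model's `do_init` anchor.
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_config()].
#' @param qc A [qc_config()].
#' @param pond_id,date Identifiers carried into the result.
#' @param data_gap Set `TRUE` when the day's forcing contains interpolated
#'   gaps long enough to invalidate the fit; adds the `data_gap` flag.
#' @param keep_chain Keep the full chain in the result (default drops it).
#' @return An object of class `day_fit`: list with `pond_id`, `date`,
#'   `summary` (posterior table from [summarize_chain()]), `gpp`, `er`,
#'   `sigma` (posterior medians), `rmse`, `r2`, `acceptance_rate`,
#'   `qc_flags` (character vector) and `retained` (TRUE iff no flags).
#' @export
fit_day <- function(forcing, observed, mcmc = mcmc_config(),
                    priors = prior_config(), qc = qc_config(),
                    pond_id = "pond", date = NULL, data_gap = FALSE,
                    keep_chain = FALSE) {
  stopifnot(inherits(forcing, "day_forcing"))
  n <- forcing$n
  if (length(observed) != n) {
    stop("pond-day ", pond_id, " ", format(date), ": `observed` must have ",
         n, " points", call. = FALSE)
  }
  forcing$do_init <- observed[1]
  # linear decomposition mO = base + gpp * U + er * V + (do_init - obs_1) * W
  base <- simulate_do(list(gpp = 0, er = 0), forcing)
  u <- simulate_do(list(gpp = 1, er = 0), forcing) - base
  v <- base - simulate_do(list(gpp = 0, er = -1), forcing)
  f2 <- forcing
  f2$do_init <- observed[1] + 1
  w <- simulate_do(list(gpp = 0, er = 0), f2) - base
  idx <- seq_len(n)
  y <- observed - base[idx]
  xmat <- cbind(u[idx], v[idx], w[idx])
  xty <- crossprod(xmat, y)
  xtx <- crossprod(xmat)
  syy <- sum(y * y)
  d0_ref <- observed[1]
  target <- function(theta) {
    s <- theta[[3]]
    if (s <= 0) return(-Inf)
    b <- c(theta[[1]], theta[[2]], theta[[4]] - d0_ref)
    rss <- syy - 2 * sum(b * xty) + sum(b * (xtx %*% b))
    if (rss < 0) rss <- 0
    -n / 2 * log(2 * pi * s * s) - rss / (2 * s * s) +
      log_prior(theta[[1]], theta[[2]], s, priors)
  }
  day_mcmc <- mcmc
  if (!"do_init" %in% names(day_mcmc$init)) {
    day_mcmc$init <- c(day_mcmc$init, do_init = unname(observed[1]))
    day_mcmc$proposal_sd <- c(day_mcmc$proposal_sd, do_init = 0.02)
  }
  tryCatch(
    chain <- metropolis_sample(day_mcmc, target),
    error = function(cond) {
      stop("pond-day ", pond_id, " ", format(date), ": ",
           conditionMessage(cond), call. = FALSE)
    }
  )
  summ <- summarize_chain(chain, day_mcmc$burn_in)
  med <- stats::setNames(summ$median, summ$parameter)
  mod <- (base + med[["gpp"]] * u + med[["er"]] * v +
            (med[["do_init"]] - d0_ref) * w)[idx]
  rmse <- sqrt(mean((observed - mod)^2))
  r2 <- if (stats::sd(observed) == 0 || stats::sd(mod) == 0) 0
        else stats::cor(observed, mod)^2
  fit <- structure(
    list(pond_id = pond_id, date = date, summary = summ,
         gpp = unname(med[["gpp"]]), er = unname(med[["er"]]),
         sigma = unname(med[["sigma"]]),
         rmse = rmse, r2 = r2,
         acceptance_rate = chain$acceptance_rate,
         converged = isTRUE(attr(summ, "converged")),
         data_gap = isTRUE(data_gap),
         qc_flags = character(), retained = NA,
         chain = if (keep_chain) chain else NULL),
    class = "day_fit"
  )
  filter_day(fit, qc)
}

#' Resolve the quality-control flags of a day fit
#'
#' Applies the day-level filters: `negative_gpp` when the posterior-median GPP
#' is below zero, `poor_fit` when r-squared falls below `r2_min` or RMSE
#' exceeds `rmse_max` (boundary values are kept), `no_convergence` when any
#' split R-hat is missing or above `rhat_max`, and `data_gap` when flagged at
#' fit time. A day is retained iff it has no flags.
#'
#' @param fit A `day_fit` from [fit_day()].
#' @param qc A [qc_config()].
#' @return The `day_fit` with `qc_flags` and `retained` resolved.
#' @export
filter_day <- function(fit, qc = qc_config()) {
  stopifnot(inherits(fit, "day_fit"))
  flags <- character()
  if (fit$gpp < 0) flags <- c(flags, "negative_gpp")
  if (fit$r2 < qc$r2_min || fit$rmse > qc$rmse_max) {
    flags <- c(flags, "poor_fit")
  }
  rhat <- fit$summary$rhat
  if (any(!is.finite(rhat)) || any(rhat > qc$rhat_max)) {
    flags <- c(flags, "no_convergence")
  }
  if (isTRUE(fit$data_gap)) flags <- c(flags, "data_gap")
  fit$qc_flags <- flags
  fit$retained <- length(flags) == 0
  fit
}

#' @export
print.day_fit <- function(x, ...) {
  cat(sprintf(
    "<day_fit> %s %s: GPP %.2f, ER %.2f, sigma %.3f | r2 %.3f rmse %.3f | %s\n",
    x$pond_id, if (is.null(x$date)) "" else format(x$date),
    x$gpp, x$er, x$sigma, x$r2, x$rmse,
    if (x$retained) "retained" else paste(x$qc_flags, collapse = ",")))
  invisible(x)
}

#' Collect day fits into a data frame
#'
#' @param fits A list of `day_fit` objects.
#' @return A data frame with one row per pond-day: identifiers, posterior
#'   medians and 95% intervals, fit diagnostics, QC flags and retention.
#' @export
day_fits_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    s <- f$summary
    g <- function(p, col) s[[col]][s$parameter == p]
    data.frame(pond_id = f$pond_id,
               date = if (is.null(f$date)) NA else as.Date(f$date),
               gpp = f$gpp, gpp_lower = g("gpp", "lower"),
               gpp_upper = g("gpp", "upper"),
               er = f$er, er_lower = g("er", "lower"),
               er_upper = g("er", "upper"),
               sigma = f$sigma, rmse = f$rmse, r2 = f$r2,
               rhat_max = max(s$rhat),
               acceptance_rate = f$acceptance_rate,
               qc_flags = paste(f$qc_flags, collapse = ";"),
               retained = f$retained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
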