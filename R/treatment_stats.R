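#' Assign calendar dates to treatment periods
#'
#' @param dates Vector of `Date`s.
#' @param periods Period table (`period`, `start`, `end`), e.g. from
#'   [scenario_periods()].
#' @return Character vector of period labels (`NA` outside all periods).
#' @export
assign_period <- function(dates, periods) {
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(periods))) {
    sel <- dates >= periods$start[i] & dates <= periods$end[i]
    out[sel] <- periods$period[i]
  }
  out
}

#' Pond-by-period means of daily response variables
#'
#' Aggregates daily pond values (retained day fits and daily drivers) to one
#' mean per pond, period and variable -- the table the treatment statistics
#' run on. The number of contributing days is reported per cell; a pond with
#' no retained days in a period yields a missing cell, listed in the
#' `"missing_cells"` attribute.
#'
#' @param values Data frame of daily values with columns `pond_id`, `group`,
#'   `date`, `variable`, `value` (e.g. from [experiment_daily_values()]).
#' @param periods Period table (`period`, `start`, `end`).
#' @return Data frame (`pond_id`, `group`, `period`, `variable`, `mean`,
#'   `n_days`), one row per pond x period x variable with data; attribute
#'   `"missing_cells"` names empty cells.
#' @export
period_means <- function(values, periods) {
  need <- c("pond_id", "group", "date", "variable", "value")
  if (!all(need %in% names(values))) {
    stop("`values` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  values$period <- assign_period(as.Date(values$date), periods)
  values <- values[!is.na(values$period) & !is.na(values$value), ]
  agg <- stats::aggregate(value ~ pond_id + group + period + variable,
                          data = values, FUN = mean)
  cnt <- stats::aggregate(value ~ pond_id + group + period + variable,
                          data = values, FUN = length)
  out <- agg
  names(out)[names(out) == "value"] <- "mean"
  out$n_days <- cnt$value
  out$period <- factor(out$period, levels = periods$period)
  out <- out[order(out$variable, out$period, out$group, out$pond_id), ]
  rownames(out) <- NULL
  full <- expand.grid(pond_id = unique(values$pond_id),
                      period = periods$period,
                      variable = unique(values$variable),
                      stringsAsFactors = FALSE)
  have <- paste(out$pond_id, out$period, out$variable)
  missing <- full[!paste(full$pond_id, full$period, full$variable) %in% have, ]
  attr(out, "missing_cells") <- missing
  out
}

#' Control-vs-treatment t-test within one period
#'
#' The default `"paired"` mode reproduces a 4-pair design (df = n - 1): ponds
#' are paired by the rank of the response within their group and the mean of
#' the pairwise differences (control minus treatment) is tested. `"welch"`
#' gives the unpaired unequal-variance test. Zero variance of the paired
#' differences leaves the statistic undefined and is reported as degenerate
#' rather than raising an error.
#'
#' @param table An experiment table from [period_means()].
#' @param variable Variable to test (e.g. `"GPP"`).
#' @param period Period label (e.g. `"p50"`).
#' @param pairing `"paired"` or `"welch"`.
#' @return One-row data frame: `test`, `variable`, `scope`, `statistic`,
#'   `df1`, `df2`, `p_value`, `n`, `degenerate`.
#' @export
period_t_test <- function(table, variable, period,
                          pairing = c("paired", "welch")) {
  pairing <- match.arg(pairing)
  sel <- table$variable == variable & table$period == period
  x <- table$mean[sel & table$group == "control"]
  y <- table$mean[sel & table$group == "treatment"]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two ponds per group in period ", period,
         call. = FALSE)
  }
  if (pairing == "paired") {
    if (length(x) != length(y)) {
      stop("paired mode needs equal group sizes", call. = FALSE)
    }
    d <- sort(x) - sort(y)   # pair ponds by within-group rank
    n <- length(d)
    if (stats::sd(d) == 0) {
      return(test_row("t_paired", variable, period, NA_real_, n - 1, NA,
                      NA_real_, n, degenerate = TRUE))
    }
    tt <- stats::t.test(sort(x), sort(y), paired = TRUE)
    test_row("t_paired", variable, period, unname(tt$statistic),
             unname(tt$parameter), NA, tt$p.value, n)
  } else {
    tt <- stats::t.test(x, y)
    test_row("t_welch", variable, period, unname(tt$statistic),
             unname(tt$parameter), NA, tt$p.value, length(x))
  }
}

test_row <- function(test, variable, scope, statistic, df1, df2, p, n,
                     degenerate = FALSE) {
  data.frame(test = test, variable = variable, scope = scope,
             statistic = statistic, df1 = df1, df2 = df2, p_value = p,
             n = n, degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom. Zero variance in either argument
#' is reported as degenerate.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param variable,scope Labels carried into the result row.
#' @return One-row data frame as in [period_t_test()], with `statistic` = r.
#' @export
pearson_r <- function(x, y, variable = "r", scope = "") {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_row("pearson", variable, scope, NA_real_,
                    length(x) - 2, NA, NA_real_, length(x),
                    degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  test_row("pearson", variable, scope, unname(ct$estimate),
           unname(ct$parameter), NA, ct$p.value, length(x))
}

#' Group-by-period interaction from repeated-measures ANOVA
#'
#' Two-way repeated-measures ANOVA with pond as the subject, period as the
#' within-subject factor and group (control/treatment) as the between-subject
#' factor; returns the group x period interaction. With g groups, k periods
#' and P ponds the interaction has (k - 1) numerator and (k - 1)(P - g)
#' denominator degrees of freedom -- (2, 12) for 8 ponds, 2 groups, 3
#' periods. The Greenhouse-Geisser epsilon and corrected p-value are reported
#' alongside, but the uncorrected df are the headline. Missing cells are an
#' error; no imputation is attempted.
#'
#' @param table An experiment table from [period_means()].
#' @param variable Variable to test.
#' @return One-row data frame as in [period_t_test()] plus `gg_epsilon` and
#'   `p_gg`.
#' @export
rm_anova_interaction <- function(table, variable) {
  d <- table[table$variable == variable, ]
  d$pond_id <- factor(d$pond_id)
  d$group <- factor(d$group)
  d$period <- factor(d$period)
  wide <- stats::xtabs(mean ~ pond_id + period, data = d)
  if (any(stats::xtabs(~ pond_id + period, data = d) != 1)) {
    stop("incomplete pond x period table for ", variable,
         "; missing cells are not imputed", call. = FALSE)
  }
  fit <- stats::aov(mean ~ group * period + Error(pond_id), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  ix <- trimws(rownames(within)) == "group:period"
  f <- within[ix, "F value"]
  df1 <- within[ix, "Df"]
  df2 <- within[trimws(rownames(within)) == "Residuals", "Df"]
  p <- within[ix, "Pr(>F)"]
  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the repeated measures
  k <- nlevels(d$period)
  covs <- lapply(levels(d$group), function(g) {
    rows <- levels(d$pond_id)[tapply(as.character(d$group), d$pond_id,
                                     `[`, 1) == g]
    stats::cov(wide[rows, , drop = FALSE])
  })
  pond_group <- tapply(as.character(d$group), d$pond_id, `[`, 1)
  ng <- vapply(levels(d$group), function(g) sum(pond_group == g), 0)
  s <- Reduce(`+`, Map(`*`, covs, as.numeric(ng) - 1)) / (sum(ng) - length(ng))
  cmat <- stats::contr.helmert(k)
  cmat <- qr.Q(qr(cmat))  # orthonormal contrasts
  m <- t(cmat) %*% s %*% cmat
  eps <- sum(diag(m))^2 / ((k - 1) * sum(m^2))
  out <- test_row("rm_anova_interaction", variable, "group:period",
                  f, df1, df2, p, nlevels(d$pond_id))
  out$gg_epsilon <- eps
  out$p_gg <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  out
}
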