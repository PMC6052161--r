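make_values <- function(gpp_by_pond) {
  # two days per period per pond, GPP only
  periods <- scenario_periods(small_scenario())
  rows <- list()
  for (p in names(gpp_by_pond)) {
    grp <- if (startsWith(p, "C")) "control" else "treatment"
    for (k in 1:3) {
      vals <- gpp_by_pond[[p]][[k]]
      rows[[length(rows) + 1]] <- data.frame(
        pond_id = p, group = grp,
        date = periods$start[k] + seq_along(vals) - 1,
        variable = "GPP", value = vals, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("period means average the retained days per pond and period", {
  periods <- scenario_periods(small_scenario())
  vals <- make_values(list(C1 = list(c(2, 4), c(3, 5), c(1, 1))))
  tab <- period_means(vals, periods)
  expect_equal(tab$mean[tab$period == "p10"], 3)
  expect_equal(tab$mean[tab$period == "p50"], 4)
  expect_equal(tab$n_days, rep(2L, 3))
  # an excluded day simply never enters the values table
  vals2 <- vals[-1, ]
  tab2 <- period_means(vals2, periods)
  expect_equal(tab2$mean[tab2$period == "p10"], 4)
  expect_equal(tab2$n_days[tab2$period == "p10"], 1L)
})

test_that("period means equal an independent group-by recomputation", {
  exp <- generate_experiment(small_scenario(seed = 4))
  tr <- exp$truth
  vals <- data.frame(pond_id = tr$pond_id, group = tr$group, date = tr$date,
                     variable = "GPP", value = tr$gpp,
                     stringsAsFactors = FALSE)
  tab <- period_means(vals, exp$periods)
  # brute-force oracle over every cell
  for (i in seq_len(nrow(tab))) {
    p <- exp$periods[exp$periods$period == tab$period[i], ]
    sel <- tr$pond_id == tab$pond_id[i] & tr$date >= p$start &
      tr$date <= p$end
    expect_equal(tab$mean[i], sum(tr$gpp[sel]) / sum(sel))
  }
  expect_equal(nrow(attr(tab, "missing_cells")), 0)
})

test_that("missing pond-period cells are flagged", {
  periods <- scenario_periods(small_scenario())
  vals <- make_values(list(C1 = list(c(2, 4), c(3, 5), c(1, 1))))
  vals <- vals[vals$date < periods$start[3], ]   # drop the ice-free period
  tab <- period_means(vals, periods)
  miss <- attr(tab, "missing_cells")
  expect_equal(miss$period, "ice_free")
  expect_equal(miss$pond_id, "C1")
})

test_that("the paired t-test reproduces the hand-computed 4-pair design", {
  periods <- scenario_periods(small_scenario())
  tab <- data.frame(
    pond_id = c(paste0("C", 1:4), paste0("T", 1:4)),
    group = rep(c("control", "treatment"), each = 4),
    period = "p50", variable = "GPP",
    mean = c(2, 3, 4, 6, 1, 2, 3, 4), n_days = 10)
  res <- period_t_test(tab, "GPP", "p50", pairing = "paired")
  # diffs after rank pairing are (1, 1, 1, 2): t = 1.25 / (0.5/2) = 5
  expect_equal(res$statistic, 5)
  expect_equal(res$df1, 3)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n, 4)
})

test_that("welch mode gives t = 0 for identical groups", {
  tab <- data.frame(
    pond_id = c(paste0("C", 1:4), paste0("T", 1:4)),
    group = rep(c("control", "treatment"), each = 4),
    period = "p10", variable = "GPP",
    mean = rep(c(2, 3, 4, 6), 2), n_days = 10)
  res <- period_t_test(tab, "GPP", "p10", pairing = "welch")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a constant shift between groups degenerates the paired test", {
  tab <- data.frame(
    pond_id = c(paste0("C", 1:4), paste0("T", 1:4)),
    group = rep(c("control", "treatment"), each = 4),
    period = "p10", variable = "GPP",
    mean = c(2, 3, 4, 6, 2, 3, 4, 6) + rep(c(0.5, 0), each = 4),
    n_days = 10)
  res <- period_t_test(tab, "GPP", "p10", pairing = "paired")
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))
  expect_equal(res$df1, 3)
})

test_that("pearson r matches hand computation and the affine property", {
  expect_equal(pearson_r(1:10, 2 * (1:10))$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 5)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$statistic, hand)
  expect_equal(res$df1, 2)
  # invariant to affine transforms (up to the sign of the slope)
  expect_equal(pearson_r(10 - 2 * x, y)$statistic, -hand)
  expect_equal(pearson_r(x, 0.1 * y + 7)$statistic, hand)
  expect_true(pearson_r(rep(1, 5), 1:5)$degenerate)
})

test_that("the RM-ANOVA interaction has design-determined df", {
  withr::local_seed(10)
  tab <- expand.grid(pond_id = c(paste0("C", 1:4), paste0("T", 1:4)),
                     period = c("p10", "p50", "ice_free"),
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(startsWith(tab$pond_id, "C"), "control", "treatment")
  tab$variable <- "GPP"
  tab$mean <- rnorm(24)
  res <- rm_anova_interaction(tab, "GPP")
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 12)
  # df depend on the design shape only, never the values
  tab$mean <- runif(24, 100, 200)
  res2 <- rm_anova_interaction(tab, "GPP")
  expect_equal(res2[, c("df1", "df2")], res[, c("df1", "df2")])
  expect_true(res2$gg_epsilon > 0.5 && res2$gg_epsilon <= 1 + 1e-9)
})

test_that("the interaction F equals a hand sums-of-squares decomposition", {
  withr::local_seed(22)
  ponds <- c(paste0("C", 1:4), paste0("T", 1:4))
  y <- matrix(rnorm(24, 5), nrow = 8,
              dimnames = list(ponds, c("p10", "p50", "ice_free")))
  tab <- data.frame(
    pond_id = rep(ponds, 3),
    group = rep(ifelse(startsWith(ponds, "C"), "control", "treatment"), 3),
    period = rep(colnames(y), each = 8),
    variable = "GPP", mean = as.vector(y), stringsAsFactors = FALSE)
  res <- rm_anova_interaction(tab, "GPP")
  # independent split-plot decomposition
  grand <- mean(y)
  gmask <- startsWith(ponds, "C")
  mean_gp <- rbind(colMeans(y[gmask, ]), colMeans(y[!gmask, ]))
  mean_g <- rowMeans(mean_gp)
  mean_p <- colMeans(mean_gp)          # balanced design
  ss_int <- 4 * sum((mean_gp - outer(mean_g, rep(1, 3)) -
                       outer(rep(1, 2), mean_p) + grand)^2)
  subj_dev <- rowMeans(y) - mean_g[2 - gmask]
  resid <- y
  for (i in 1:8) {
    g <- if (gmask[i]) 1 else 2
    resid[i, ] <- y[i, ] - mean_gp[g, ] - subj_dev[i]
  }
  ss_err <- sum(resid^2)
  f_oracle <- (ss_int / 2) / (ss_err / 12)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
})

test_that("randomly relabelled groups show no systematic interaction", {
  withr::local_seed(33)
  exp <- generate_experiment(scenario_config(seed = 3))
  tr <- exp$truth
  vals <- data.frame(pond_id = tr$pond_id, group = tr$group, date = tr$date,
                     variable = "GPP", value = tr$gpp,
                     stringsAsFactors = FALSE)
  ponds <- unique(vals$pond_id)
  ps <- replicate(20, {
    shuffled <- setNames(sample(rep(c("control", "treatment"), each = 4)),
                         ponds)
    v <- vals
    v$group <- shuffled[v$pond_id]
    tab <- period_means(v, exp$periods)
    rm_anova_interaction(tab, "GPP")$p_value
  })
  expect_gte(sum(ps > 0.05), 14)   # null p-values are roughly uniform
})
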