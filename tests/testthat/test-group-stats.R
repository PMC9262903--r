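# Build a measure table directly (participant x direction x speed), with a
# known group/condition mean structure plus noise.
make_table <- function(groups, n, effect = function(g, d, s) 0, sd = 1,
                       seed = 1) {
  set.seed(seed)
  grid <- expand.grid(j = seq_len(n), age_group = groups,
                      direction = c("contraction", "expansion"),
                      speed = c("low", "high"), stringsAsFactors = FALSE)
  grid$participant_id <- paste0(grid$age_group, "_p", grid$j)
  grid$dv <- mapply(effect, grid$age_group, grid$direction, grid$speed) +
    rnorm(nrow(grid), 0, sd)
  grid
}

test_that("partial eta squared and its CI reproduce known values", {
  expect_equal(partial_eta_sq(51.470, 1, 247), 0.1724, tolerance = 1e-3)
  expect_equal(partial_eta_sq(12.073, 12, 247), 0.3697, tolerance = 1e-3)
  expect_equal(partial_eta_sq(0, 3, 100), 0)
  ci <- partial_eta_sq_ci(51.470, 1, 247)
  expect_true(ci[1] < 0.1724 && 0.1724 < ci[2])
  expect_true(ci[1] >= 0 && ci[2] < 1 && ci[1] <= ci[2])
  # tiny F: lower bound floored at zero
  ci0 <- partial_eta_sq_ci(0.1, 1, 100)
  expect_equal(ci0[1], 0)
  # the CI level is honored: narrower at 80% than 95%
  ci80 <- partial_eta_sq_ci(51.470, 1, 247, level = 0.80)
  expect_gt(ci80[1], ci[1]); expect_lt(ci80[2], ci[2])
})

test_that("two-level within-participant effect equals the paired-t oracle", {
  tbl <- data.frame(
    participant_id = rep(c("p1", "p2", "p3"), each = 2),
    age_group = "adult",
    direction = rep(c("contraction", "expansion"), 3),
    speed = "low",
    dv = c(1, 2, 2, 4, 3, 3))
  d <- data.frame(participant = factor(tbl$participant_id),
                  direction = factor(tbl$direction), dv = tbl$dv)
  fit <- flowgaze:::.fit_lmm(dv ~ direction + (1 | participant), d)
  an <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  # paired t on differences (1, 2, 0): t = 1.732..., F = t^2 = 3
  tt <- t.test(c(1, 2, 0))
  expect_equal(an[["F value"]], unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(an$DenDF, 2, tolerance = 1e-6)
})

test_that("constant response yields F ~ 0 for every term", {
  tbl <- make_table(c("1y", "5y", "adult"), 4)
  tbl$dv <- 3.3
  res <- suppressMessages(fit_threeway_lmm(tbl, "dv", df_method = "satterthwaite"))
  expect_true(all(res$F < 1e-6))
  expect_true(all(res$partial_eta_sq < 1e-6))
})

test_that("three-way LMM recovers a planted direction effect with KR df", {
  eff <- function(g, d, s) 4 + ifelse(d == "expansion", 1.2, 0)
  tbl <- make_table(c("1y", "5y", "adult"), 10, eff, sd = 0.8, seed = 42)
  res <- fit_threeway_lmm(tbl, "dv", df_method = "kenward-roger")
  expect_s3_class(res, "anova_result")
  expect_equal(attr(res, "df_method"), "kenward-roger")
  expect_setequal(res$term, c("age", "direction", "speed", "age:direction",
                              "age:speed", "direction:speed",
                              "age:direction:speed"))
  dir_row <- res[res$term == "direction", ]
  expect_lt(dir_row$p, 0.001)
  expect_equal(dir_row$df1, 1)
  expect_true(all(res$eta_ci_low <= res$eta_ci_high))
  # the interval brackets the estimate for the clearly significant term
  expect_true(dir_row$eta_ci_low < dir_row$partial_eta_sq &
                dir_row$partial_eta_sq < dir_row$eta_ci_high)
  # single-level factors cannot support the factorial model
  expect_error(fit_threeway_lmm(tbl[1:4, ], "dv"), "at least 2 levels")
})

test_that("simple effects are signed expansion minus contraction", {
  eff <- function(g, d, s) {
    bias <- c("1y" = -1.5, "5y" = 1.5, "adult" = 1.5)[g]
    4 + ifelse(d == "expansion", bias / 2, -bias / 2)
  }
  tbl <- make_table(c("1y", "5y", "adult"), 12, eff, sd = 0.7, seed = 7)
  se <- suppressMessages(
    simple_effects_by_age(tbl, "dv", df_method = "satterthwaite"))
  expect_equal(nrow(se), 3)
  expect_lt(se$estimate[se$age_group == "1y"], 0)
  expect_gt(se$estimate[se$age_group == "5y"], 0)
  expect_gt(se$estimate[se$age_group == "adult"], 0)
  expect_true(all(se$p[abs(se$estimate) > 1] < 0.05))
  # a null group stays near zero
  tbl0 <- make_table(c("1y", "5y"), 12, function(g, d, s) 4, sd = 0.7, seed = 8)
  se0 <- suppressMessages(
    simple_effects_by_age(tbl0, "dv", df_method = "satterthwaite"))
  expect_true(all(abs(se0$estimate) < 0.5))
})

test_that("pairwise age comparisons enumerate all pairs with corrected alpha", {
  groups <- AGE_GROUPS
  eff <- function(g, d, s) 3
  tbl <- make_table(groups, 3, eff, sd = 0.5, seed = 3)
  pw <- suppressMessages(
    pairwise_ages(tbl, "dv", "expansion", df_method = "satterthwaite"))
  expect_equal(nrow(pw), choose(13, 2))
  expect_equal(pw$alpha_corrected[1], 0.05 / 78)
  # identical groups: nothing flagged
  expect_false(any(pw$significant))
  # planted age difference is detected
  eff2 <- function(g, d, s) ifelse(g == "adult", 8, 3)
  tbl2 <- make_table(c("1y", "2y", "adult"), 8, eff2, sd = 0.5, seed = 4)
  pw2 <- suppressMessages(
    pairwise_ages(tbl2, "dv", "expansion", df_method = "satterthwaite"))
  expect_equal(nrow(pw2), 3)
  hit <- pw2$significant[pw2$group1 == "adult" | pw2$group2 == "adult"]
  expect_true(all(hit))
})

test_that("asymmetry t-tests run one cell per group x speed against 0.5", {
  set.seed(21)
  idx <- expand.grid(j = 1:20, age_group = AGE_GROUPS,
                     speed = c("low", "high"), stringsAsFactors = FALSE)
  idx$participant_id <- paste0(idx$age_group, "_p", idx$j)
  idx$index <- 0.5
  res <- asymmetry_ttests(idx)
  expect_equal(nrow(res), 26)
  expect_equal(res$alpha_corrected[1], 0.05 / 26)
  expect_true(all(is.na(res$t)))  # zero variance cells are excluded, noted
  expect_true(all(res$note == "zero variance"))
  # known-mean cell: t matches the closed form
  idx$index <- 0.5 + rnorm(nrow(idx), 0.1, 0.05)
  res2 <- asymmetry_ttests(idx)
  cell <- idx$index[idx$age_group == "1y" & idx$speed == "low"]
  t_hand <- (mean(cell) - 0.5) / (sd(cell) / sqrt(length(cell)))
  expect_equal(res2$t[res2$age_group == "1y" & res2$speed == "low"], t_hand)
  expect_true(all(res2$n == 20))
  # undefined indices are dropped listwise
  idx$index[idx$age_group == "2y"] <- NA
  res3 <- asymmetry_ttests(idx)
  expect_true(all(res3$n[res3$age_group == "2y"] == 0))
  expect_true(all(is.na(res3$p[res3$age_group == "2y"])))
})

test_that("benchmark ANOVA: mixed model on trials, aov fallback on means", {
  set.seed(61)
  tbl <- expand.grid(trial = 1:2, j = 1:8,
                     age_group = c("1y", "5y", "adult"),
                     stringsAsFactors = FALSE)
  tbl$participant_id <- paste0(tbl$age_group, "_p", tbl$j)
  tbl$latency_aoi_s <- 1 + rnorm(nrow(tbl), 0, 0.3)
  res <- suppressMessages(benchmark_anova(tbl, df_method = "satterthwaite"))
  expect_equal(attr(res, "model_type"), "lmm")
  expect_equal(res$df1, 2)
  expect_gt(res$p, 0.001)  # age-independent latencies
  # averaged (one row per participant): falls back to fixed-effects ANOVA
  avg <- aggregate(latency_aoi_s ~ participant_id + age_group, tbl, mean)
  res2 <- benchmark_anova(avg)
  expect_equal(attr(res2, "model_type"), "aov")
  expect_equal(res2$df2, nrow(avg) - 3)
  # constant dv
  avg$latency_aoi_s <- 2
  expect_lt(benchmark_anova(avg)$F, 1e-10)
  expect_error(benchmark_anova(avg[avg$age_group == "1y", ]), "2 age groups")
})

test_that("per-speed two-way refit exposes age x direction structure", {
  eff <- function(g, d, s) {
    if (s == "low") 4
    else 4 + ifelse(d == "expansion", 1, 0) * ifelse(g == "adult", 1.5, 0)
  }
  tbl <- make_table(c("1y", "adult"), 12, eff, sd = 0.6, seed = 13)
  lo <- suppressMessages(fit_twoway_lmm(tbl, "dv", "low", "satterthwaite"))
  hi <- suppressMessages(fit_twoway_lmm(tbl, "dv", "high", "satterthwaite"))
  expect_setequal(lo$term, c("age", "direction", "age:direction"))
  expect_gt(lo[lo$term == "age:direction", "p"], 0.05)
  expect_lt(hi[hi$term == "age:direction", "p"], 0.05)
})
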