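#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the proportion of effect-plus-error
#' variance attributable to the effect.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1)`. Vectorized.
#' @export
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 > 0), all(df2 > 0))
  f * df1 / (f * df1 + df2)
}

#' Confidence interval for partial eta squared
#'
#' Inverts the noncentral-F distribution: the confidence limits on the
#' noncentrality parameter are the values for which the observed F sits at
#' the upper/lower tail probability, converted to eta_p^2 via
#' `ncp / (ncp + df1 + df2 + 1)`. The lower bound is floored at 0.
#'
#' @inheritParams partial_eta_sq
#' @param level confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
partial_eta_sq_ci <- function(f, df1, df2, level = 0.95) {
  alpha <- 1 - level
  ncp_limit <- function(prob) {
    # ncp with P(F' <= f | ncp) == prob; 0 if already below at ncp = 0
    if (stats::pf(f, df1, df2, ncp = 0) < prob) return(0)
    hi <- 10
    while (stats::pf(f, df1, df2, ncp = hi) > prob && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(n) stats::pf(f, df1, df2, ncp = n) - prob,
                   c(0, hi), tol = 1e-8)$root
  }
  lo <- ncp_limit(1 - alpha / 2)
  hi <- ncp_limit(alpha / 2)
  c(lo / (lo + df1 + df2 + 1), hi / (hi + df1 + df2 + 1))
}

# Fit a mixed model with sum-to-zero contrasts (required for meaningful
# type-III tests) and return the lmerTest fit.
.fit_lmm <- function(formula, data) {
  facs <- names(Filter(is.factor, data))
  for (f in facs) stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  lmerTest::lmer(formula, data = data, REML = TRUE)
}

.prepare_measure_table <- function(table, dv) {
  stopifnot(dv %in% names(table))
  need <- c("participant_id", "age_group", "direction", "speed")
  if (!all(need %in% names(table)))
    stop("measure table must have columns ", paste(need, collapse = ", "))
  d <- data.frame(participant = factor(table$participant_id),
                  age = factor(table$age_group,
                               levels = intersect(AGE_GROUPS,
                                                  unique(table$age_group))),
                  direction = factor(table$direction,
                                     levels = c("contraction", "expansion")),
                  speed = factor(table$speed, levels = c("low", "high")),
                  dv = table[[dv]])
  if (anyNA(d$age)) d$age <- factor(table$age_group)
  d[!is.na(d$dv), ]
}

# Factorial terms of a fully crossed design with their numerator df, for the
# zero-variance short-circuit where no model can (or need) be fitted.
.degenerate_anova <- function(d, factors) {
  dfs <- vapply(factors, function(f) nlevels(droplevels(d[[f]])) - 1L, 1L)
  terms <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)))
  df1 <- vapply(strsplit(terms, ":"), function(tt) prod(dfs[tt]), numeric(1))
  df2 <- nrow(d) - sum(df1) - 1
  res <- data.frame(term = terms, F = 0, df1 = df1, df2 = df2, p = 1,
                    stringsAsFactors = FALSE)
  res$partial_eta_sq <- 0
  res$eta_ci_low <- 0; res$eta_ci_high <- 0
  class(res) <- c("anova_result", "data.frame")
  res
}

.check_factorial <- function(d, factors) {
  for (f in factors)
    if (nlevels(droplevels(d[[f]])) < 2)
      stop("need at least 2 levels of '", f, "' to fit the factorial model")
}

.resolve_ddf <- function(df_method) {
  df_method <- match.arg(df_method, c("kenward-roger", "satterthwaite"))
  if (df_method == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    message("Kenward-Roger unavailable (pbkrtest not installed); ",
            "falling back to Satterthwaite")
    df_method <- "satterthwaite"
  }
  df_method
}

#' Three-way mixed-model ANOVA
#'
#' The study's main inferential model: a linear mixed-effects model of one
#' dependent measure with the full age x flow-direction x dot-speed factorial
#' as fixed effects and a participant random intercept, tested with type-III
#' F tests. Denominator degrees of freedom use Kenward-Roger by default
#' (Satterthwaite as documented fallback/option). Each term is reported with
#' partial eta squared and its noncentral-F confidence interval.
#'
#' @param table long data.frame with columns participant_id, age_group,
#'   direction, speed and the dependent variable (repetition means, four rows
#'   per participant; see [aggregate_scores()]).
#' @param dv name of the dependent-variable column.
#' @param df_method `"kenward-roger"` or `"satterthwaite"`.
#' @param ci_level confidence level for the eta_p^2 interval.
#' @return An `anova_result` data.frame: term, F, df1, df2, p,
#'   partial_eta_sq, eta_ci_low, eta_ci_high, plus attributes `df_method` and
#'   `model` (the lmerTest fit).
#' @export
fit_threeway_lmm <- function(table, dv, df_method = "kenward-roger",
                             ci_level = 0.95) {
  d <- .prepare_measure_table(table, dv)
  .check_factorial(d, c("age", "direction", "speed"))
  if (min(table(d$age)) < 2)
    stop("need at least 2 observations per age group")
  if (stats::var(d$dv) < 1e-12)  # constant response: nothing to explain
    return(.degenerate_anova(d, c("age", "direction", "speed")))
  df_method <- .resolve_ddf(df_method)
  fit <- .fit_lmm(dv ~ age * direction * speed + (1 | participant), d)
  if (lme4::isSingular(fit, tol = 1e-5))
    message("random-intercept variance estimated at (or near) zero")
  an <- stats::anova(fit, type = 3, ddf = ifelse(df_method == "kenward-roger",
                                                 "Kenward-Roger",
                                                 "Satterthwaite"))
  res <- data.frame(term = rownames(an), F = an[["F value"]],
                    df1 = an$NumDF, df2 = an$DenDF,
                    p = an[["Pr(>F)"]], stringsAsFactors = FALSE)
  res$partial_eta_sq <- partial_eta_sq(res$F, res$df1, res$df2)
  ci <- t(vapply(seq_len(nrow(res)), function(i)
    partial_eta_sq_ci(res$F[i], res$df1[i], res$df2[i], ci_level),
    numeric(2)))
  res$eta_ci_low <- ci[, 1]; res$eta_ci_high <- ci[, 2]
  attr(res, "df_method") <- df_method
  attr(res, "model") <- fit
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Simple main effect of flow direction within each age group
#'
#' Expansion-vs-contraction contrasts of least-squares means per age group
#' (marginal over speed), from the full three-way mixed model. Estimates are
#' signed expansion minus contraction, so positive values indicate an
#' expansion bias on the measure.
#'
#' @inheritParams fit_threeway_lmm
#' @param model optionally a prefitted model (attribute of
#'   [fit_threeway_lmm()] output) to avoid refitting.
#' @return data.frame: age_group, estimate, SE, df, t, p.
#' @export
simple_effects_by_age <- function(table, dv, df_method = "kenward-roger",
                                  model = NULL) {
  d <- .prepare_measure_table(table, dv)
  if (any(table(d$age) == 0)) stop("empty age cell")
  df_method <- .resolve_ddf(df_method)
  fit <- if (is.null(model))
    .fit_lmm(dv ~ age * direction * speed + (1 | participant), d) else model
  emm <- emmeans::emmeans(fit, ~ direction | age,
                          lmer.df = df_method,
                          lmerTest.limit = 1e5, pbkrtest.limit = 1e5)
  ctr <- summary(emmeans::contrast(emm, method = list(expansion_minus_contraction = c(-1, 1))))
  data.frame(age_group = as.character(ctr$age), estimate = ctr$estimate,
             SE = ctr$SE, df = ctr$df, t = ctr$t.ratio, p = ctr$p.value,
             stringsAsFactors = FALSE)
}

#' Pairwise age-group comparisons within a flow direction
#'
#' All C(13, 2) = 78 pairwise least-squares-mean comparisons between age
#' groups within one flow direction, flagged against the Bonferroni-corrected
#' threshold alpha / 78 (raw p-values are returned alongside the flags, as in
#' the study's reporting).
#'
#' @inheritParams simple_effects_by_age
#' @param direction `"expansion"` or `"contraction"`.
#' @param alpha familywise alpha before correction.
#' @return data.frame: group1, group2, estimate, SE, df, t, p,
#'   alpha_corrected, significant.
#' @export
pairwise_ages <- function(table, dv, direction = c("expansion", "contraction"),
                          df_method = "kenward-roger", alpha = 0.05,
                          model = NULL) {
  direction <- match.arg(direction)
  d <- .prepare_measure_table(table, dv)
  df_method <- .resolve_ddf(df_method)
  fit <- if (is.null(model))
    .fit_lmm(dv ~ age * direction * speed + (1 | participant), d) else model
  emm <- emmeans::emmeans(fit, ~ age | direction,
                          lmer.df = df_method,
                          lmerTest.limit = 1e5, pbkrtest.limit = 1e5)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  prs <- prs[as.character(prs$direction) == direction, ]
  nm <- do.call(rbind, strsplit(as.character(prs$contrast), " - "))
  n_pairs <- nrow(prs)
  out <- data.frame(group1 = gsub("^age|[()]", "", nm[, 1]),
                    group2 = gsub("^age|[()]", "", nm[, 2]),
                    estimate = prs$estimate, SE = prs$SE, df = prs$df,
                    t = prs$t.ratio, p = prs$p.value,
                    stringsAsFactors = FALSE)
  out$alpha_corrected <- alpha / n_pairs
  out$significant <- out$p < out$alpha_corrected
  out
}

#' One-sample tests of the asymmetry index against 0.5
#'
#' Two-tailed one-sample t-tests of the per-participant expansion/contraction
#' asymmetry index against the no-bias value 0.5, one per age group x speed
#' cell (26 cells in the full design), flagged against the Bonferroni
#' threshold alpha / n_cells. Participants with an undefined index (zero
#' total looking time) are excluded listwise; cells with fewer than two
#' defined indices are reported as NA and flagged in `note`.
#'
#' @param index_table data.frame from [asymmetry_table()]: participant_id,
#'   age_group, speed, index.
#' @param alpha familywise alpha before correction.
#' @return data.frame: age_group, speed, n, mean_index, t, df, p,
#'   alpha_corrected, significant, note.
#' @export
asymmetry_ttests <- function(index_table, alpha = 0.05) {
  cells <- unique(index_table[, c("age_group", "speed")])
  cells <- cells[order(match(cells$age_group, AGE_GROUPS), cells$speed), ]
  n_cells <- nrow(cells)
  rows <- lapply(seq_len(n_cells), function(i) {
    x <- index_table$index[index_table$age_group == cells$age_group[i] &
                           index_table$speed == cells$speed[i]]
    x <- x[!is.na(x)]
    if (length(x) < 2 || stats::sd(x) == 0) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
      note <- if (length(x) < 2) "fewer than 2 defined indices" else "zero variance"
    } else {
      tt <- stats::t.test(x, mu = 0.5)
      note <- ""
    }
    data.frame(age_group = cells$age_group[i], speed = cells$speed[i],
               n = length(x), mean_index = if (length(x)) mean(x) else NA_real_,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$alpha_corrected <- alpha / n_cells
  out$significant <- !is.na(out$p) & out$p < out$alpha_corrected
  out[, c("age_group", "speed", "n", "mean_index", "t", "df", "p",
          "alpha_corrected", "significant", "note")]
}

#' One-way benchmark ANOVA on age
#'
#' Tests whether first-entry latency to the benchmark square differs across
#' age groups — the control for basic gaze-following ability. With
#' trial-level data (more than one row per participant) a mixed model with a
#' participant random intercept is fitted; with one (averaged) row per
#' participant the random intercept is unidentifiable and a fixed-effects
#' one-way ANOVA is used instead.
#'
#' @param table data.frame with columns participant_id, age_group and the dv.
#' @param dv dependent-variable column name (default benchmark latency).
#' @param df_method denominator-df method for the mixed-model branch.
#' @return One-row data.frame: term, F, df1, df2, p, partial_eta_sq, plus
#'   attribute `model_type` (`"lmm"` or `"aov"`).
#' @export
benchmark_anova <- function(table, dv = "latency_aoi_s",
                            df_method = "kenward-roger") {
  stopifnot(dv %in% names(table))
  d <- data.frame(participant = factor(table$participant_id),
                  age = factor(table$age_group,
                               levels = intersect(AGE_GROUPS,
                                                  unique(table$age_group))),
                  dv = table[[dv]])
  if (anyNA(d$age)) d$age <- factor(table$age_group)
  d <- d[!is.na(d$dv), ]
  if (nlevels(droplevels(d$age)) < 2) stop("need at least 2 age groups")
  if (stats::var(d$dv) < 1e-12) {
    res <- data.frame(term = "age", F = 0,
                      df1 = nlevels(droplevels(d$age)) - 1,
                      df2 = nrow(d) - nlevels(droplevels(d$age)), p = 1)
    res$partial_eta_sq <- 0
    attr(res, "model_type") <- "degenerate"
    return(res)
  }
  per_part <- max(table(d$participant))
  if (per_part > 1) {
    df_method <- .resolve_ddf(df_method)
    fit <- .fit_lmm(dv ~ age + (1 | participant), d)
    an <- stats::anova(fit, type = 3,
                       ddf = ifelse(df_method == "kenward-roger",
                                    "Kenward-Roger", "Satterthwaite"))
    res <- data.frame(term = "age", F = an[["F value"]], df1 = an$NumDF,
                      df2 = an$DenDF, p = an[["Pr(>F)"]])
    type <- "lmm"
  } else {
    an <- summary(stats::aov(dv ~ age, data = d))[[1]]
    res <- data.frame(term = "age", F = an[["F value"]][1],
                      df1 = an$Df[1], df2 = an$Df[2],
                      p = an[["Pr(>F)"]][1])
    type <- "aov"
  }
  res$partial_eta_sq <- partial_eta_sq(res$F, res$df1, res$df2)
  attr(res, "model_type") <- type
  res
}

#' Two-way mixed-model ANOVA (age x flow direction)
#'
#' The per-speed follow-up model used to decompose a higher-order
#' interaction: age x direction fixed factorial with a participant random
#' intercept, fitted to one speed condition's data.
#'
#' @inheritParams fit_threeway_lmm
#' @param speed_level which speed condition to subset (`"low"` or `"high"`).
#' @return An `anova_result` data.frame as in [fit_threeway_lmm()].
#' @export
fit_twoway_lmm <- function(table, dv, speed_level = c("low", "high"),
                           df_method = "kenward-roger", ci_level = 0.95) {
  speed_level <- match.arg(speed_level)
  d <- .prepare_measure_table(table[table$speed == speed_level, ], dv)
  .check_factorial(d, c("age", "direction"))
  if (stats::var(d$dv) < 1e-12)
    return(.degenerate_anova(d, c("age", "direction")))
  df_method <- .resolve_ddf(df_method)
  fit <- .fit_lmm(dv ~ age * direction + (1 | participant), d)
  an <- stats::anova(fit, type = 3, ddf = ifelse(df_method == "kenward-roger",
                                                 "Kenward-Roger",
                                                 "Satterthwaite"))
  res <- data.frame(term = rownames(an), F = an[["F value"]],
                    df1 = an$NumDF, df2 = an$DenDF, p = an[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  res$partial_eta_sq <- partial_eta_sq(res$F, res$df1, res$df2)
  ci <- t(vapply(seq_len(nrow(res)), function(i)
    partial_eta_sq_ci(res$F[i], res$df1[i], res$df2[i], ci_level),
    numeric(2)))
  res$eta_ci_low <- ci[, 1]; res$eta_ci_high <- ci[, 2]
  attr(res, "df_method") <- df_method
  attr(res, "model") <- fit
  class(res) <- c("anova_result", "data.frame")
  res
}
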