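#' Dichotomize values at their median
#'
#' `"high"` iff strictly above the median (even n: mean of the middle
#' pair); ties at the median go to `"low"`, keeping "high" strictly above
#' the median — the conservative direction for enrichment claims.
#'
#' @param values named numeric vector (>= 2 samples, not all identical).
#' @return named character vector of `"high"` / `"low"`.
#' @export
dichotomize_by_median <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (length(unique(values)) == 1)
    abort("degenerate split: all values identical")
  m <- median(values)
  setNames(ifelse(values > m, "high", "low"), names(values))
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Haldane-Anscombe correction: when any cell
#' is zero, 0.5 is added to all four cells before computing both the OR and
#' its standard error `sqrt(1/a' + 1/b' + 1/c' + 1/d')`. Exact tables are
#' left untouched.
#'
#' @param a,b,c,d non-negative integer cells (a = high/case, b =
#'   high/control, c = low/case, d = low/control).
#' @return list: `or`, `log_or`, `se`, `cells` (possibly corrected).
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(cells, is_count, logical(1))))
    abort("cells must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    abort("a whole row or column of the 2x2 table is zero")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  list(or = unname(or), log_or = unname(log(or)),
       se = unname(sqrt(sum(1 / cells))), cells = cells)
}

#' Per-cohort effect for meta-analysis
#'
#' @param cohort cohort identifier.
#' @inheritParams odds_ratio_2x2
#' @return a `cohort_effect`: cohort id, 2x2 table, `log_or`, `se`.
#' @export
cohort_effect <- function(cohort, a, b, c, d) {
  est <- odds_ratio_2x2(a, b, c, d)
  structure(list(cohort = cohort, table = c(a = a, b = b, c = c, d = d),
                 log_or = est$log_or, se = est$se),
            class = "cohort_effect")
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-cohort log odds ratios with weights `w_i = 1 / se_i^2`:
#' pooled = `sum(w logOR) / sum(w)`, 95% CI `pooled +/- 1.96 / sqrt(sum w)`,
#' Cochran's `Q = sum w (logOR_i - pooled)^2`, and
#' `I^2 = max(0, (Q - df) / Q) * 100` (0 when all effects are equal).
#'
#' @param effects list of [cohort_effect()]s (>= 1, all `se > 0`).
#' @return a `meta_result`: `pooled_log_or`, `pooled_or`, `ci_low`,
#'   `ci_high` (OR scale), `z`, `p`, `Q`, `df`, `i_squared`, `effects`
#'   data frame.
#' @export
fixed_effect_meta <- function(effects) {
  if (inherits(effects, "cohort_effect")) effects <- list(effects)
  stopifnot(length(effects) >= 1)
  log_or <- vapply(effects, `[[`, numeric(1), "log_or")
  se <- vapply(effects, `[[`, numeric(1), "se")
  if (any(!is.finite(se)) || any(se <= 0)) abort("all standard errors must be positive")
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  q <- sum(w * (log_or - pooled)^2)
  df <- length(effects) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  z <- pooled / se_pooled
  per <- data.frame(
    cohort = vapply(effects, function(e) as.character(e$cohort), character(1)),
    or = exp(log_or), log_or = log_or, se = se,
    ci_low = exp(log_or - 1.96 * se), ci_high = exp(log_or + 1.96 * se),
    weight = w / sum(w), stringsAsFactors = FALSE)
  structure(list(pooled_log_or = pooled, pooled_or = exp(pooled),
                 ci_low = exp(pooled - 1.96 * se_pooled),
                 ci_high = exp(pooled + 1.96 * se_pooled),
                 z = z, p = 2 * pnorm(-abs(z)),
                 Q = q, df = df, i_squared = i2, effects = per),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d cohort(s)\n", nrow(x$effects)))
  cat(sprintf("  pooled OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  heterogeneity: Q = %.3f on %d df, I^2 = %.1f%%\n",
              x$Q, x$df, x$i_squared))
  invisible(x)
}

#' Median-split guild-abundance meta-analysis across cohorts
#'
#' Convenience pipeline for the cross-cohort risk analysis: within each
#' cohort, samples are dichotomized at the cohort median of the guild
#' abundance, the 2x2 table (high/low x case/control) is formed, and the
#' per-cohort log odds ratios are pooled with [fixed_effect_meta()].
#'
#' @param abundance named numeric vector of per-sample guild abundance.
#' @param condition named `"case"`/`"control"` vector over the same samples.
#' @param cohort named cohort-id vector over the same samples.
#' @return a `meta_result`.
#' @export
guild_meta_analysis <- function(abundance, condition, cohort) {
  ids <- names(abundance)
  stopifnot(!is.null(ids), setequal(ids, names(condition)),
            setequal(ids, names(cohort)))
  condition <- condition[ids]; cohort <- cohort[ids]
  effects <- lapply(split(ids, cohort), function(s) {
    grp <- dichotomize_by_median(abundance[s])
    cond <- condition[s]
    cohort_effect(cohort[s][1L],
                  a = sum(grp == "high" & cond == "case"),
                  b = sum(grp == "high" & cond == "control"),
                  c = sum(grp == "low" & cond == "case"),
                  d = sum(grp == "low" & cond == "control"))
  })
  fixed_effect_meta(unname(effects))
}

#' Covariate-adjusted group difference in a continuous outcome
#'
#' Ordinary least squares of `outcome` on a high/low group indicator plus
#' covariates. Reports the group coefficient (difference high - low) with
#' 95% CI and two-sided p, plus the covariate terms. The design matrix
#' must be full rank; collinear columns are reported by name.
#'
#' @param outcome numeric response per sample.
#' @param group `"high"`/`"low"` per sample.
#' @param covariates optional numeric data frame / matrix of adjustment
#'   variables.
#' @return an `outcome_model`: coefficient table (term, estimate, ci_low,
#'   ci_high, p), `n`, and the underlying `lm` fit.
#' @export
adjusted_group_difference <- function(outcome, group, covariates = NULL) {
  stopifnot(length(outcome) == length(group))
  group <- factor(group, levels = c("low", "high"))
  df <- data.frame(outcome = outcome, group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= ncol(df) + 1) abort("too few samples for the design")
  x <- model.matrix(~ ., data = df[, -1L, drop = FALSE])
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    abort("rank-deficient design; collinear column(s): ", fmt_ids(dropped))
  }
  fit <- lm(outcome ~ ., data = df)
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                    ci_low = ci[, 1L], ci_high = ci[, 2L], p = sm[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, group_term = "grouphigh", n = n,
                 fit = fit), class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  g <- x$coefficients[x$coefficients$term == x$group_term, ]
  cat(sprintf("adjusted group difference (n = %d): %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
              x$n, g$estimate, g$ci_low, g$ci_high, g$p))
  invisible(x)
}
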