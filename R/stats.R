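#' Shapiro-Wilk normality test
#'
#' Royston's AS R94 approximation (coefficients and p-value), for sample sizes
#' 3 to 2000; constant input is rejected as an error.
#'
#' @param values Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 2000) stop("Shapiro-Wilk requires 3 <= n <= 2000")
  if (stats::sd(values) == 0) stop("Shapiro-Wilk undefined for constant input")
  r <- stats::shapiro.test(values)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Two-way ANOVA for a genotype x diet design
#'
#' Type II sums of squares (via `car::Anova` on the full factorial linear
#' model), which reduce to the classical balanced-design decomposition when
#' cell sizes are equal and remain well defined for the mildly unbalanced
#' cohorts (6--8 per group) this layer targets.
#'
#' @param values Response vector.
#' @param genotype,diet Factor (or coercible) vectors of matching length.
#' @return An `anova_result`: data frame with one row per effect (genotype,
#'   diet, interaction) holding F, df pair and p, plus residual df as
#'   attribute `df_residual`.
#' @export
two_way_anova <- function(values, genotype, diet) {
  genotype <- factor(genotype); diet <- factor(diet)
  if (nlevels(genotype) < 2 || nlevels(diet) < 2)
    stop("both factors need at least two levels")
  if (any(table(genotype, diet) == 0)) stop("empty factor cell")
  fit <- stats::lm(values ~ genotype * diet)
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  a <- tryCatch(car::Anova(fit, type = 2), error = function(e) e)
  if (inherits(a, "error")) {
    # degenerate zero-residual input: fall back to explicit type II model
    # comparisons; F is 0 for zero-SS effects, +Inf otherwise
    rss <- function(mm) sum(stats::lm.fit(mm, values)$residuals^2)
    r_gd <- rss(stats::model.matrix(~genotype + diet))
    ss <- c(genotype = rss(stats::model.matrix(~diet)) - r_gd,
            diet = rss(stats::model.matrix(~genotype)) - r_gd,
            interaction = r_gd - rss(stats::model.matrix(~genotype * diet)))
    zero <- abs(ss) < 1e-10 * max(abs(values)^2, 1)
    out <- data.frame(effect = names(ss),
                      df = c(nlevels(genotype) - 1, nlevels(diet) - 1,
                             (nlevels(genotype) - 1) * (nlevels(diet) - 1)),
                      df_residual = fit$df.residual,
                      F = ifelse(zero, 0, Inf),
                      p = ifelse(zero, 1, 0), row.names = NULL)
    attr(out, "df_residual") <- fit$df.residual
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  eff <- c("genotype", "diet", "genotype:diet")
  out <- data.frame(effect = c("genotype", "diet", "interaction"),
                    df = a[eff, "Df"],
                    df_residual = a["Residuals", "Df"],
                    F = a[eff, "F value"],
                    p = a[eff, "Pr(>F)"], row.names = NULL)
  attr(out, "df_residual") <- a["Residuals", "Df"]
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey's honestly-significant-difference comparisons
#'
#' Tukey-Kramer studentized-range comparisons of all group pairs:
#' `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with adjusted
#' p-values from the studentized range distribution.
#'
#' @param values Response vector.
#' @param groups Group labels (every group needs n >= 2).
#' @return Data frame with one row per pair: `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  n <- table(groups)
  if (nlevels(groups) < 2) stop("at least two groups required")
  if (any(n < 2)) stop("every group needs at least 2 observations")
  means <- tapply(values, groups, mean)
  df_res <- length(values) - nlevels(groups)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_res
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$diff <- as.numeric(means[out$group2] - means[out$group1])
  se <- as.numeric(sqrt(mse / 2 * (1 / n[out$group1] + 1 / n[out$group2])))
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = nlevels(groups), df = df_res,
                             lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sample t-test against a reference value
#'
#' Used for values normalized to a control group and compared to 100 percent.
#'
#' @param values Numeric sample (n >= 2, nonzero variance).
#' @param mu Reference value (default 100).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
one_sample_t <- function(values, mu = 100) {
  if (length(values) < 2) stop("need at least 2 observations")
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  r <- stats::t.test(values, mu = mu)
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (the conventional default of the
#' commercial software this layer mirrors); Welch's correction via
#' `var_equal = FALSE`.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Use pooled variance (default TRUE).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (var_equal && stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance: t statistic undefined")
  r <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Normalize responses to the within-genotype control-diet mean
#'
#' Expresses each Western-diet animal's value as percent of its own genotype's
#' control-diet group mean, the form tested against 100 percent with
#' [one_sample_t()].
#'
#' @param values Response vector.
#' @param genotype,diet Factor vectors; `control_diet` names the reference
#'   diet level.
#' @param control_diet Reference diet label (default `"CD"`).
#' @return Numeric vector: percent values for non-control-diet samples, NA
#'   for control-diet samples.
#' @export
normalize_to_genotype <- function(values, genotype, diet, control_diet = "CD") {
  out <- rep(NA_real_, length(values))
  for (g in unique(genotype)) {
    ctrl <- values[genotype == g & diet == control_diet]
    if (!length(ctrl)) stop("no control-diet samples for genotype ", g)
    sel <- genotype == g & diet != control_diet
    out[sel] <- 100 * values[sel] / mean(ctrl)
  }
  out
}
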