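# Shared fixtures and independent oracles. Everything is generated in code;
# the default cohort is built once per test session and reused.

.fixtures <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]])) {
    co <- simulate_cohort(cohort_config(seed = seed))
    refd <- lapply(co$spectra, reference_to_lactate)
    co$normalized <- total_sum_normalize(bin_cohort(refd))
    .fixtures[[key]] <- co
  }
  .fixtures[[key]]
}

# config with all stochastic terms off, for exact-recovery checks
noiseless_config <- function(...) {
  cohort_config(noise_sd = 0, shift_jitter_sd = 0, amplitude_cv = 0, ...)
}

# a single isolated singlet, for closed-form effect-injection checks; with
# anchor = TRUE a large invariant resonance is added so that total-sum
# normalization leaves the probe's group contrast (almost) intact
singlet_panel <- function(center = 2.5, amp = 5,
                          multipliers = c("WT/CD" = 1, "WT/WD" = 1.3,
                                          "KO/CD" = 0.8, "KO/WD" = 1.04),
                          anchor = FALSE, anchor_amp = 100 * amp) {
  flat <- stats::setNames(rep(1, length(multipliers)), names(multipliers))
  specs <- list(metabolite_spec("probe", list(multiplet(center, 1, linewidth = 0.01)),
                                amp, multipliers))
  if (anchor)
    specs <- c(specs, list(metabolite_spec(
      "anchor", list(multiplet(7.0, 1, linewidth = 0.01)), anchor_amp, flat)))
  specs
}

# one-sided two-sample KS statistic, written independently of the package
ks_D_oracle <- function(true_acc, perm_acc) {
  pts <- sort(unique(c(true_acc, perm_acc)))
  max(c(vapply(pts, function(t) mean(perm_acc <= t) - mean(true_acc <= t),
               numeric(1)), 0))
}

# Type II two-way ANOVA through explicit design-matrix least squares:
# each effect's SS is the residual-SS drop when adding it to the model that
# respects marginality (main effects adjusted for the other main effect,
# interaction adjusted for both).
anova_type2_oracle <- function(y, g, d) {
  g <- factor(g); d <- factor(d)
  rss <- function(mm) {
    fit <- lm.fit(mm, y)
    sum(fit$residuals^2)
  }
  mm_g  <- model.matrix(~g)
  mm_d  <- model.matrix(~d)
  mm_gd <- model.matrix(~g + d)
  mm_f  <- model.matrix(~g * d)
  rss_f <- rss(mm_f)
  df_res <- length(y) - ncol(mm_f)
  ss <- c(genotype = rss(mm_d) - rss(mm_gd),
          diet = rss(mm_g) - rss(mm_gd),
          interaction = rss(mm_gd) - rss_f)
  df <- c((nlevels(g) - 1), (nlevels(d) - 1),
          (nlevels(g) - 1) * (nlevels(d) - 1))
  F <- (ss / df) / (rss_f / df_res)
  data.frame(effect = names(ss), df = df, F = unname(F),
             p = unname(stats::pf(F, df, df_res, lower.tail = FALSE)))
}

# two fixed 10-value accuracy samples whose one-sided KS permutation p was
# computed by exhaustive enumeration of all choose(20,10) label splits
ks_oracle_cases <- list(
  moderate = list(
    true = c(0.943, 0.42, 0.496, 0.538, 0.454, 0.458, 0.712, 0.582, 0.623, 0.928),
    perm = c(0.504, 0.858, 0.792, 0.499, 0.734, 0.52, 0.316, 0.404, 0.449, 0.598),
    D = 0.2, p_exact = 0.6818182),
  separated = list(
    true = c(0.803, 0.852, 0.729, 0.741, 0.944, 0.775, 0.956, 0.9, 0.846, 0.77),
    perm = c(0.417, 0.465, 0.346, 0.474, 0.385, 0.501, 0.478, 0.589, 0.441, 0.434),
    D = 1, p_exact = 5.412544e-06)
)
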