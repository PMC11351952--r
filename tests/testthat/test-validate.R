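null_data <- function(n = 14, J = 30, seed = 99) {
  set.seed(seed)
  list(X = matrix(stats::rnorm(n * J), n, J), y = rep(c("A", "B"), each = n / 2))
}

test_that("stratified folds partition all samples and keep classes in training", {
  y <- rep(c("A", "B"), each = 7)
  set.seed(1)
  for (i in 1:20) {
    f <- metabocv:::make_valid_folds(y, 8)
    expect_length(f, 14)
    expect_setequal(unique(f), 1:8)        # every fold non-empty
    for (k in 1:8)
      expect_setequal(unique(y[f != k]), c("A", "B"))
    # class balance: fold sizes differ by at most one
    expect_lte(diff(range(table(f))), 1)
  }
})

test_that("model count equals external_folds x repetitions", {
  d <- null_data()
  arm <- repeated_external_cv(d$X, d$y, cv_config(external_folds = 4,
                                                  repetitions = 5, seed = 2))
  expect_equal(nrow(arm$records), 20)
  expect_true(all(arm$records$accuracy >= 0 & arm$records$accuracy <= 1))
  expect_true(all(arm$records$n_orth %in% 0:2))
})

test_that("runs are reproducible for an identical seed", {
  d <- null_data()
  cfg <- cv_config(repetitions = 5, seed = 7)
  expect_identical(repeated_external_cv(d$X, d$y, cfg),
                   repeated_external_cv(d$X, d$y, cfg))
  expect_identical(permutation_null(d$X, d$y, cfg),
                   permutation_null(d$X, d$y, cfg))
})

test_that("classes from one distribution show no skill above chance", {
  # models within one dataset are correlated, so dataset means spread widely
  # (and sit slightly below 0.5: the anti-learning effect of CV on null data
  # at n = 14); the defensible property is the absence of positive skill,
  # judged across independent datasets with a t-type error estimate
  ms <- vapply(1:8, function(i) {
    d <- null_data(seed = 30 + i)
    arm <- repeated_external_cv(d$X, d$y,
                                cv_config(repetitions = 10, seed = 130 + i))
    mean(arm$records$accuracy)
  }, numeric(1))
  expect_lt(mean(ms) - 0.5, 3 * stats::sd(ms) / sqrt(length(ms)))
  # and the significance machinery agrees: a null comparison is never called
  d <- null_data(seed = 77)
  rep0 <- validate_comparison(d$X, d$y, cv_config(repetitions = 25, seed = 14))
  expect_false(rep0$significant)
})

test_that("widely separated classes are classified almost perfectly", {
  d <- null_data(seed = 12)
  d$X[, 1] <- d$X[, 1] + ifelse(d$y == "A", 10, 0)   # 10 sd apart on one bin
  arm <- repeated_external_cv(d$X, d$y, cv_config(repetitions = 25, seed = 9))
  expect_gte(mean(arm$records$accuracy), 0.95)
  expect_gte(mean(arm$records$sensitivity, na.rm = TRUE), 0.9)
  expect_gte(mean(arm$records$specificity, na.rm = TRUE), 0.9)
})

test_that("permuting labels destroys even a strong signal", {
  d <- null_data(seed = 13)
  d$X[, 1] <- d$X[, 1] + ifelse(d$y == "A", 10, 0)
  perm <- permutation_null(d$X, d$y, cv_config(repetitions = 25, seed = 10))
  expect_lt(mean(perm$records$accuracy), 0.6)
})

test_that("held-out scaling statistics come from the training split only", {
  seen <- integer(0)
  local_mocked_bindings(
    pareto_stats = function(x) {
      seen <<- c(seen, nrow(x))
      mu <- colMeans(x)
      sd <- sqrt(pmax(colSums(x^2) - nrow(x) * mu^2, 0) / (nrow(x) - 1))
      list(center = mu, scale = ifelse(sd > 0, sqrt(sd), 1))
    },
    .package = "metabocv"
  )
  d <- null_data()
  invisible(repeated_external_cv(d$X, d$y, cv_config(repetitions = 2, seed = 3)))
  expect_gt(length(seen), 0)
  expect_true(all(seen < nrow(d$X)))   # never the full cohort
})

test_that("KS closed forms: identical arrays and disjoint supports", {
  x <- c(0.4, 0.5, 0.6, 0.7)
  same <- ks_significance(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  disj <- ks_significance(c(0.8, 0.9, 1), c(0.1, 0.2, 0.3))
  expect_equal(disj$D, 1)
  expect_error(ks_significance(numeric(0), x), "empty")
})

test_that("KS p agrees with the exhaustive label-permutation oracle", {
  for (case in ks_oracle_cases) {
    ks <- ks_significance(case$true, case$perm)
    expect_equal(ks$D, ks_D_oracle(case$true, case$perm), tolerance = 1e-12)
    expect_equal(ks$D, case$D)
    # asymptotic formula vs exact enumeration: small-sample slack 0.02 absolute
    expect_lt(abs(ks$p - case$p_exact), 0.02)
  }
})

test_that("run_all_pairwise produces four complete reports", {
  set.seed(44)
  groups <- rep(c("WT/CD", "WT/WD", "KO/CD", "KO/WD"), each = 5)
  X <- matrix(stats::rnorm(20 * 15), 20, 15)
  X[, 1] <- X[, 1] + ifelse(groups %in% c("KO/CD", "KO/WD"), 3, 0)
  X <- abs(X) + 0.1
  m <- new_bin_matrix(X / rowSums(X),
                      cbind(lo = seq(1, by = 0.02, length.out = 15),
                            hi = seq(1.02, by = 0.02, length.out = 15)),
                      state = "normalized")
  design <- data.frame(sample_id = paste0("s", 1:20), group = groups)
  cfg <- cv_config(external_folds = 5, repetitions = 4, seed = 11)
  reps <- run_all_pairwise(m, design, cfg)
  expect_length(reps, 4)
  for (r in reps) {
    expect_s3_class(r, "validation_report")
    expect_equal(nrow(r$records), 20)
    expect_equal(nrow(r$perm_records), 20)
    expect_length(r$vip_mean, 15)
    expect_true(all(r$vip_mean >= 0))
  }
  s <- attr(reps, "summary")
  expect_equal(nrow(s), 4)
  expect_named(s, c("comparison", "models", "accuracy", "sensitivity",
                    "specificity", "perm_accuracy", "ks_D", "ks_p", "significant"))
  expect_error(run_all_pairwise(m, data.frame(sample_id = "a", group = "X"), cfg),
               "missing")
})
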