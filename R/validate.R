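#' Cross-validation configuration
#'
#' Defaults reproduce the published scheme: 8 external folds x 100 repetitions
#' (800 models per comparison), 7-fold internal cross-validation on each
#' training split to choose the orthogonal-component count over `0..max_orth`.
#'
#' @param external_folds Outer folds per repetition.
#' @param repetitions Number of random re-partitions.
#' @param internal_folds Inner folds for hyperparameter selection.
#' @param max_orth Largest orthogonal-component count considered.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A `cv_config` object.
#' @export
cv_config <- function(external_folds = 8, repetitions = 100,
                      internal_folds = 7, max_orth = 2, seed = NULL) {
  if (internal_folds < 2) stop("internal_folds must be >= 2")
  if (external_folds < 2) stop("external_folds must be >= 2")
  structure(list(external_folds = external_folds, repetitions = repetitions,
                 internal_folds = internal_folds, max_orth = max_orth,
                 seed = seed),
            class = "cv_config")
}

# Stratified fold assignment: within each class the members are shuffled,
# then all samples are dealt round-robin to folds with a counter continuing
# across classes, so fold sizes differ by at most one and each training
# split keeps both classes for the small cohorts this scheme targets.
stratified_folds <- function(y, k) {
  ord <- integer(0)
  for (cl in unique(y)) {
    members <- which(y == cl)
    ord <- c(ord, members[sample.int(length(members))])
  }
  out <- integer(length(y))
  out[ord] <- ((seq_along(ord) - 1L) %% k) + 1L
  out
}

make_valid_folds <- function(y, k, max_tries = 10) {
  for (i in seq_len(max_tries)) {
    folds <- stratified_folds(y, k)
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- y[folds != f]
      if (length(folds[folds == f]) == 0L || length(unique(tr)) < 2L) {
        ok <- FALSE; break
      }
    }
    if (ok) return(folds)
  }
  stop("could not build folds with both classes in every training split")
}

# Evaluate predictive models for every orthogonal-component count 0..max_orth
# in one sweep: after each deflation step the predictive component on the
# current residual is fitted and the held-out scores recorded.
opls_path <- function(Xtr, yc, ypm, Xte, max_orth) {
  scores <- matrix(0, nrow(Xte), max_orth + 1L)
  thr <- numeric(max_orth + 1L)
  X <- Xtr; Xt <- Xte
  for (k in 0:max_orth) {
    w <- crossprod(X, yc)[, 1]
    w <- w / sqrt(sum(w^2))
    t <- X %*% w
    tt <- sum(t^2)
    b <- sum(t * yc) / tt
    str <- b * t[, 1]
    ste <- b * (Xt %*% w)[, 1]
    thr[k + 1L] <- (mean(str[ypm == 1]) + mean(str[ypm == -1])) / 2
    scores[, k + 1L] <- ste
    if (k < max_orth) {
      p <- crossprod(X, t)[, 1] / tt
      wo <- p - sum(w * p) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) {            # residual has no orthogonal variation left
        for (kk in (k + 1):max_orth) {
          thr[kk + 1L] <- thr[k + 1L]; scores[, kk + 1L] <- ste
        }
        break
      }
      wo <- wo / nwo
      to <- X %*% wo
      po <- crossprod(X, to)[, 1] / sum(to^2)
      X <- X - to %*% t(po)
      Xt <- Xt - (Xt %*% wo) %*% t(po)
    }
  }
  list(scores = scores, thr = thr)
}

# Internal CV on the training split only; ties resolved toward fewer
# orthogonal components (which.max returns the first maximum).
choose_n_orth <- function(X, y, internal_folds, max_orth, pos) {
  n <- nrow(X)
  folds <- make_valid_folds(y, min(internal_folds, n))
  correct <- numeric(max_orth + 1L)
  for (f in seq_len(max(folds))) {
    te <- folds == f
    st <- pareto_stats(X[!te, , drop = FALSE])
    Xtr <- apply_pareto(X[!te, , drop = FALSE], st)
    Xte <- apply_pareto(X[te, , drop = FALSE], st)
    ypm <- ifelse(y[!te] == pos, 1, -1)
    path <- opls_path(Xtr, ypm - mean(ypm), ypm, Xte, max_orth)
    actual <- y[te] == pos
    for (kk in 0:max_orth)
      correct[kk + 1L] <-
        correct[kk + 1L] + sum((path$scores[, kk + 1L] >= path$thr[kk + 1L]) == actual)
  }
  which.max(correct) - 1L
}

cv_arm <- function(X, y, cfg, permute = FALSE, pos = NULL) {
  X <- as_matrix_values(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2) stop("exactly two classes are required")
  if (is.null(pos)) pos <- classes[1]
  n <- nrow(X); J <- ncol(X)
  nrec <- cfg$external_folds * cfg$repetitions
  rec <- data.frame(repetition = integer(nrec), fold = integer(nrec),
                    n_orth = integer(nrec), accuracy = numeric(nrec),
                    sensitivity = numeric(nrec), specificity = numeric(nrec))
  vip_sum <- numeric(J)
  i <- 0L
  for (r in seq_len(cfg$repetitions)) {
    yr <- if (permute) sample(y) else y
    folds <- make_valid_folds(yr, cfg$external_folds)
    for (f in seq_len(cfg$external_folds)) {
      te <- folds == f
      k_star <- choose_n_orth(X[!te, , drop = FALSE], yr[!te],
                              cfg$internal_folds, cfg$max_orth, pos)
      st <- pareto_stats(X[!te, , drop = FALSE])
      Xtr <- apply_pareto(X[!te, , drop = FALSE], st)
      Xte <- apply_pareto(X[te, , drop = FALSE], st)
      ypm <- ifelse(yr[!te] == pos, 1, -1)
      yc <- ypm - mean(ypm)
      core <- opls_core(Xtr, yc, k_star)
      thr <- (mean(core$scores[ypm == 1]) + mean(core$scores[ypm == -1])) / 2
      ste <- opls_scores(core, Xte)
      pred <- ste >= thr
      actual <- yr[te] == pos
      i <- i + 1L
      rec$repetition[i] <- r; rec$fold[i] <- f; rec$n_orth[i] <- k_star
      rec$accuracy[i] <- mean(pred == actual)
      rec$sensitivity[i] <- if (any(actual)) mean(pred[actual]) else NA_real_
      rec$specificity[i] <- if (any(!actual)) mean(!pred[!actual]) else NA_real_
      vip_sum <- vip_sum + sqrt(J) * abs(core$w_pred) / sqrt(sum(core$w_pred^2))
    }
  }
  list(records = rec, vip_mean = vip_sum / nrec, positive_class = pos)
}

#' Repeated external cross-validation of a two-class OPLS-DA comparison
#'
#' For each repetition the samples are randomly partitioned into stratified
#' external folds. For each fold, Pareto scaling statistics are computed on
#' the training split only, the orthogonal-component count is chosen by
#' internal cross-validation within the training split, a model is fitted on
#' the full training split and accuracy/sensitivity/specificity are measured
#' on the held-out fold. `external_folds * repetitions` models are fitted
#' (800 at the defaults) and their VIP vectors averaged.
#'
#' @param X Samples x bins matrix in the total-sum-normalized state (a
#'   `bin_matrix` or plain matrix); scaling happens per training split.
#' @param y Two-class labels, one per row of `X`.
#' @param cfg A [cv_config()]; `cfg$seed` makes the run reproducible.
#' @param positive_class Label treated as "positive" for sensitivity
#'   (default: first class named in `y`).
#' @return List with `records` (one row per model), `vip_mean` and
#'   `positive_class`.
#' @export
repeated_external_cv <- function(X, y, cfg = cv_config(), positive_class = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cv_arm(X, y, cfg, permute = FALSE, pos = positive_class)
}

#' Permutation-null arm of the validation scheme
#'
#' Identical to [repeated_external_cv()] except that the class labels are
#' shuffled once per repetition before fold assignment, destroying any real
#' class structure; the resulting accuracies form the chance-level reference
#' distribution (mean approximately 50%).
#'
#' @inheritParams repeated_external_cv
#' @return List with `records`, `vip_mean`, `positive_class` for the
#'   permuted models.
#' @export
permutation_null <- function(X, y, cfg = cv_config(), positive_class = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cv_arm(X, y, cfg, permute = TRUE, pos = positive_class)
}

#' One-sided two-sample Kolmogorov-Smirnov comparison of accuracy arms
#'
#' Tests whether the true-model accuracies are stochastically greater than the
#' permutation-null accuracies: `D` is the supremum of (permuted ECDF - true
#' ECDF) over all thresholds and the p-value uses the asymptotic one-sided
#' Smirnov formula `exp(-2 D^2 m n / (m + n))`.
#'
#' @param true_acc,perm_acc Nonempty accuracy vectors.
#' @param alpha Significance level (default 0.001).
#' @return List with `D`, `p` and `significant`.
#' @export
ks_significance <- function(true_acc, perm_acc, alpha = 0.001) {
  if (!length(true_acc) || !length(perm_acc)) stop("empty accuracy vector")
  pts <- sort(unique(c(true_acc, perm_acc)))
  Ft <- stats::ecdf(true_acc)(pts)
  Fp <- stats::ecdf(perm_acc)(pts)
  D <- max(c(Fp - Ft, 0))
  m <- length(true_acc); n <- length(perm_acc)
  p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
  list(D = D, p = p, significant = p < alpha)
}

#' Full validation report for one pairwise comparison
#'
#' Runs the true and permutation arms with seeds derived from `cfg$seed` and
#' compares the two accuracy distributions with the one-sided KS test.
#'
#' @inheritParams repeated_external_cv
#' @param comparison Label stored on the report.
#' @param alpha KS significance level.
#' @return A `validation_report`.
#' @export
validate_comparison <- function(X, y, cfg = cv_config(), comparison = NULL,
                                positive_class = NULL, alpha = 0.001) {
  if (is.null(comparison)) comparison <- paste(unique(as.character(y)), collapse = " vs ")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  true_arm <- cv_arm(X, y, cfg, permute = FALSE, pos = positive_class)
  perm_arm <- cv_arm(X, y, cfg, permute = TRUE, pos = positive_class)
  ks <- ks_significance(true_arm$records$accuracy, perm_arm$records$accuracy,
                        alpha = alpha)
  structure(list(comparison = comparison,
                 records = true_arm$records,
                 perm_records = perm_arm$records,
                 true_accuracies = true_arm$records$accuracy,
                 perm_accuracies = perm_arm$records$accuracy,
                 vip_mean = true_arm$vip_mean,
                 positive_class = true_arm$positive_class,
                 mean_accuracy = mean(true_arm$records$accuracy),
                 sd_accuracy = stats::sd(true_arm$records$accuracy),
                 mean_sensitivity = mean(true_arm$records$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(true_arm$records$specificity, na.rm = TRUE),
                 mean_perm_accuracy = mean(perm_arm$records$accuracy),
                 ks_statistic = ks$D, ks_p = ks$p, significant = ks$significant,
                 alpha = alpha),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$comparison, "\n",
      sprintf(" models: %d true + %d permuted\n",
              nrow(x$records), nrow(x$perm_records)),
      sprintf(" accuracy %.3f (perm %.3f), sens %.3f, spec %.3f\n",
              x$mean_accuracy, x$mean_perm_accuracy,
              x$mean_sensitivity, x$mean_specificity),
      sprintf(" KS D = %.3f, p = %.3g -> %s\n", x$ks_statistic, x$ks_p,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

default_comparisons <- function(groups = c("WT/CD", "WT/WD", "KO/CD", "KO/WD")) {
  list(c(groups[1], groups[2]),   # diet effect in wild type
       c(groups[3], groups[4]),   # diet effect in knockout
       c(groups[1], groups[3]),   # genotype effect on control diet
       c(groups[2], groups[4]))   # genotype effect on Western diet
}

#' Run the four pairwise group comparisons of a factorial cohort
#'
#' Each comparison (diet within each genotype, genotype within each diet)
#' gets its own true and permutation arms (seeds derived deterministically
#' from `cfg$seed`) and its own KS significance call.
#'
#' @param m Total-sum-normalized `bin_matrix` (or plain matrix) of all samples.
#' @param design Data frame with `sample_id` and `group` columns matching the
#'   rows of `m`.
#' @param cfg A [cv_config()].
#' @param comparisons List of label pairs; default the four factorial cells.
#' @param alpha KS significance level.
#' @return Named list of `validation_report` objects, with a summary table
#'   attached as attribute `summary` (see [summarize_reports()]).
#' @export
run_all_pairwise <- function(m, design, cfg = cv_config(),
                             comparisons = default_comparisons(), alpha = 0.001) {
  X <- as_matrix_values(m)
  if (inherits(m, "bin_matrix") && m$state != "normalized")
    stop("run_all_pairwise expects a total-sum-normalized bin matrix")
  groups <- design$group
  missing <- setdiff(unique(unlist(comparisons)), groups)
  if (length(missing))
    stop("groups missing from design: ", paste(missing, collapse = ", "))
  reports <- list()
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    sel <- groups %in% cmp
    sub_cfg <- cfg
    if (!is.null(cfg$seed)) sub_cfg$seed <- cfg$seed + 97L * i
    lab <- paste(cmp, collapse = " vs ")
    reports[[lab]] <- validate_comparison(X[sel, , drop = FALSE], groups[sel],
                                          sub_cfg, comparison = lab,
                                          positive_class = cmp[1], alpha = alpha)
  }
  attr(reports, "summary") <- summarize_reports(reports)
  reports
}

#' Summary table across validation reports
#'
#' @param reports List of `validation_report` objects.
#' @return Data frame with one row per comparison: mean accuracy, sensitivity,
#'   specificity, mean permuted accuracy, KS statistic/p and significance.
#' @export
summarize_reports <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(comparison = r$comparison, models = nrow(r$records),
               accuracy = r$mean_accuracy,
               sensitivity = r$mean_sensitivity,
               specificity = r$mean_specificity,
               perm_accuracy = r$mean_perm_accuracy,
               ks_D = r$ks_statistic, ks_p = r$ks_p,
               significant = r$significant, row.names = NULL)
  }))
}
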