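test_that("noiseless singlet lands on the grid point nearest its center", {
  cfg <- noiseless_config()
  specs <- list(metabolite_spec("lac", list(multiplet(1.33, 1, linewidth = 0.005)),
                                1, c("WT/CD" = 1, "WT/WD" = 1, "KO/CD" = 1, "KO/WD" = 1)))
  s <- simulate_spectrum(specs, "WT/CD", cfg)
  grid <- s$ppm
  expect_equal(s$ppm[which.max(s$intensity)], grid[which.min(abs(grid - 1.33))])
  expect_equal(max(s$intensity), 1, tolerance = 1e-12)
})

test_that("zero metabolites with zero noise give an all-zero trace", {
  s <- simulate_spectrum(list(), "WT/CD", noiseless_config())
  expect_true(all(s$intensity == 0))
})

test_that("a noiseless doublet peak-picks to its configured center", {
  cfg <- noiseless_config()
  specs <- list(metabolite_spec("lac",
    list(multiplet(1.33, c(1, 1), spacing = 0.01, linewidth = 0.003)),
    1, c("WT/CD" = 1, "WT/WD" = 1, "KO/CD" = 1, "KO/WD" = 1)))
  s <- simulate_spectrum(specs, "WT/CD", cfg)
  pk <- metabocv:::local_maxima(s$intensity)
  top2 <- pk[order(s$intensity[pk], decreasing = TRUE)][1:2]
  expect_equal(mean(s$ppm[top2]), 1.33, tolerance = 1e-3)
  expect_length(top2, 2)
})

test_that("a multiplet outside the grid raises an error naming the metabolite", {
  cfg <- noiseless_config(ppm_min = 2, ppm_max = 9, ppm_points = 1000)
  specs <- singlet_panel(center = 1.0)
  expect_error(simulate_spectrum(specs, "WT/CD", cfg), "probe")
})

test_that("cohort has 4 x n_per_group spectra matching the design one-to-one", {
  co <- default_cohort()
  expect_length(co$spectra, 28)
  expect_equal(as.integer(table(co$design$group)), rep(7L, 4))
  expect_identical(names(co$spectra), co$design$sample_id)
  expect_setequal(unique(co$design$genotype), c("WT", "KO"))
  expect_setequal(unique(co$design$diet), c("CD", "WD"))
})

test_that("identical seed and config give a bit-identical cohort", {
  cfg <- cohort_config(seed = 42, n_per_group = 3, ppm_points = 500)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
  expect_identical(a$design, b$design)
})

test_that("duplicate group labels are rejected", {
  expect_error(cohort_config(groups = c("A", "A", "B", "C")), "duplicate")
})

test_that("lipid-region integral is highest in KO/WD, per the injected effects", {
  co <- default_cohort()
  truth <- co$truth$amplitudes
  lipid <- truth[c("lipid_ch3", "lipid_ch2", "vldl"), ]
  expect_true(all(apply(lipid, 1, which.max) == which(colnames(truth) == "KO/WD")))
  # and the simulated spectra agree: mean raw integral over 1.24-1.34 ppm
  ints <- vapply(co$spectra, function(s) {
    sel <- s$ppm >= 1.24 & s$ppm <= 1.34
    pracma::trapz(s$ppm[sel], s$intensity[sel])
  }, numeric(1))
  gm <- tapply(ints, co$design$group, mean)
  expect_equal(names(which.max(gm)), "KO/WD")
})

test_that("noiseless region integrals reproduce group multipliers exactly", {
  mults <- c("WT/CD" = 1, "WT/WD" = 1.3, "KO/CD" = 0.8, "KO/WD" = 1.04)
  cfg <- noiseless_config(n_per_group = 3)
  co <- simulate_cohort(cfg, specs = singlet_panel(multipliers = mults))
  ints <- vapply(co$spectra, function(s) {
    sel <- s$ppm >= 2.3 & s$ppm <= 2.7
    pracma::trapz(s$ppm[sel], s$intensity[sel])
  }, numeric(1))
  gm <- tapply(ints, co$design$group, mean)[names(mults)]
  expect_equal(as.numeric(gm / gm[["WT/CD"]]), unname(mults), tolerance = 1e-6)
})

test_that("raising a group multiplier strictly raises that group's integral", {
  region_mean <- function(mult_kowd) {
    mults <- c("WT/CD" = 1, "WT/WD" = 1, "KO/CD" = 1, "KO/WD" = mult_kowd)
    co <- simulate_cohort(noiseless_config(n_per_group = 3),
                          specs = singlet_panel(multipliers = mults))
    ints <- vapply(co$spectra, function(s) {
      sel <- s$ppm >= 2.3 & s$ppm <= 2.7
      pracma::trapz(s$ppm[sel], s$intensity[sel])
    }, numeric(1))
    mean(ints[co$design$group == "KO/WD"])
  }
  vals <- vapply(c(0.5, 1, 1.5, 2), region_mean, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("OGTT simulation: zero noise reproduces group means, counts and baseline", {
  gm <- list("WT/CD" = c(5, 9, 8, 6), "WT/WD" = c(6, 11, 10, 8),
             "KO/CD" = c(5, 10, 9, 7), "KO/WD" = c(7, 13, 12, 9))
  tab <- simulate_ogtt(gm, sd = 0, n = 7, seed = 3)
  expect_equal(nrow(tab), 28)
  for (g in names(gm))
    expect_equal(unname(as.matrix(tab[tab$group == g, c("t0", "t5", "t15", "t30")])),
                 matrix(gm[[g]], 7, 4, byrow = TRUE))
  expect_error(simulate_ogtt(list(A = c(0, 5, 5, 5))), "nonpositive")
  # a flat curve has zero incremental excursion above baseline
  flat <- simulate_ogtt(list(A = c(7, 7, 7, 7)), sd = 0, n = 2)
  expect_equal(ogtt_auc(unlist(flat[1, c("t0", "t5", "t15", "t30")]),
                        method = "incremental"), 0)
})

test_that("Ct simulation inverts exactly through the comparative-Ct method", {
  groups <- c("WT/CD", "WT/WD")
  folds <- matrix(c(1, 1, 1, 2, 1, 0.5), nrow = 3, byrow = TRUE,
                  dimnames = list(c("IRA", "IRB", "PTEN"), groups))
  ct <- simulate_ct_table(folds, noise_sd = 0, n = 4, seed = 5)
  rec <- ddct_folds(ct, control_group = "WT/CD")
  for (g in rownames(folds)) {
    expect_equal(unname(rec[[g]][rec$group == "WT/CD"]), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(rec[[g]][rec$group == "WT/WD"]),
                 rep(folds[g, "WT/WD"], 4), tolerance = 1e-12)
  }
  expect_error(simulate_ct_table(folds * 0), "positive")
})
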