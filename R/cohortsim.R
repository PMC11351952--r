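#' Multiplet description for a simulated metabolite
#'
#' A multiplet is a set of Lorentzian (or Gaussian) lines sharing one linewidth,
#' placed symmetrically around a centre chemical shift.
#'
#' @param center Centre of the multiplet (ppm).
#' @param intensities Relative line intensities; normalised to sum to 1.
#' @param spacing Spacing between adjacent lines (ppm). Ignored for singlets.
#' @param linewidth Full width at half maximum of each line (ppm). Must be > 0.
#' @return A `multiplet` object (list with the four fields above).
#' @export
multiplet <- function(center, intensities = 1, spacing = 0, linewidth = 0.005) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(intensities), all(intensities > 0),
            is.numeric(spacing), length(spacing) == 1L, spacing >= 0)
  if (!is.numeric(linewidth) || length(linewidth) != 1L || linewidth <= 0)
    stop("multiplet linewidth must be a single positive number")
  structure(list(center = center,
                 intensities = intensities / sum(intensities),
                 spacing = spacing,
                 linewidth = linewidth),
            class = "multiplet")
}

#' Simulated metabolite: multiplets plus group effect structure
#'
#' @param name Metabolite label.
#' @param multiplets List of [multiplet()] objects.
#' @param base_amplitude Peak-height amplitude (arbitrary intensity units) of the
#'   whole metabolite in the reference condition.
#' @param group_multipliers Named numeric vector, one positive multiplier per
#'   cohort group; the group mean amplitude is `base_amplitude * multiplier`.
#' @return A `metabolite_spec` object.
#' @export
metabolite_spec <- function(name, multiplets, base_amplitude, group_multipliers) {
  if (inherits(multiplets, "multiplet")) multiplets <- list(multiplets)
  stopifnot(all(vapply(multiplets, inherits, logical(1), "multiplet")))
  if (any(group_multipliers <= 0))
    stop("group multipliers must be positive (metabolite ", name, ")")
  if (is.null(names(group_multipliers)))
    stop("group_multipliers must be named by group label")
  structure(list(name = name, multiplets = multiplets,
                 base_amplitude = base_amplitude,
                 group_multipliers = group_multipliers),
            class = "metabolite_spec")
}

#' Cohort simulation settings
#'
#' Defaults emulate a 2 x 2 genotype-by-diet plasma NMR study: four groups of
#' seven animals, a 0.2--9.3 ppm grid at 0.002 ppm resolution, mild baseline
#' noise, 12% biological amplitude variability and sub-gridpoint shift jitter.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param groups Four distinct group labels (genotype/diet cells).
#' @param ppm_min,ppm_max,ppm_points Chemical-shift grid specification.
#' @param noise_sd Gaussian baseline noise SD (intensity units).
#' @param shift_jitter_sd Per-sample chemical-shift jitter SD (ppm).
#' @param amplitude_cv Coefficient of variation of per-sample, per-metabolite
#'   amplitudes (biological variability).
#' @param lineshape `"lorentzian"` (NMR-physical default) or `"gaussian"`.
#' @param seed Optional integer seed used by [simulate_cohort()].
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = 7,
                          groups = c("WT/CD", "WT/WD", "KO/CD", "KO/WD"),
                          ppm_min = 0.2, ppm_max = 9.3, ppm_points = 4551,
                          noise_sd = 0.05, shift_jitter_sd = 0.002,
                          amplitude_cv = 0.12,
                          lineshape = c("lorentzian", "gaussian"),
                          seed = NULL) {
  lineshape <- match.arg(lineshape)
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  if (anyDuplicated(groups)) stop("duplicate group labels in cohort config")
  if (length(groups) != 4L) stop("exactly four group labels are required")
  if (ppm_min >= ppm_max) stop("ppm_min must be below ppm_max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_per_group = n_per_group, groups = groups,
                 ppm_min = ppm_min, ppm_max = ppm_max, ppm_points = ppm_points,
                 noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
                 amplitude_cv = amplitude_cv, lineshape = lineshape,
                 seed = seed),
            class = "cohort_config")
}

ppm_grid <- function(cfg) seq(cfg$ppm_min, cfg$ppm_max, length.out = cfg$ppm_points)

#' Default metabolite panel with genotype x diet effect structure
#'
#' Chemical-shift regions follow the plasma CPMG reference convention
#' (broad lipid CH3/CH2 and VLDL resonances around 0.8--1.3 ppm, unsaturated
#' lipid at 5.32 ppm, the lactate doublet at 1.33 ppm, alanine at 1.48 ppm,
#' branched-chain amino acids near 1 ppm, glucose ring protons 3.2--3.9 ppm
#' plus the alpha-anomeric doublet at 5.23 ppm). Default group multipliers
#' encode additive (multiplicative per factor) increases of lipids/VLDL in
#' knockout and Western-diet animals, additive decreases of lactate, alanine,
#' valine and isoleucine, and a knockout-by-diet interaction confined to
#' unsaturated lipid (up) and glucose (down).
#'
#' @param groups Group labels in the order (control, diet, genotype, both).
#' @return Named list of [metabolite_spec()] objects.
#' @export
metabolite_specs <- function(groups = c("WT/CD", "WT/WD", "KO/CD", "KO/WD")) {
  mult <- function(ctrl, diet, geno, both) {
    stats::setNames(c(ctrl, diet, geno, both), groups)
  }
  up   <- mult(1.00, 1.30, 1.30, 1.69)   # additive lipid increases
  down <- mult(1.00, 0.70, 0.70, 0.49)   # additive small-molecule decreases
  specs <- list(
    metabolite_spec("lipid_ch3",
      list(multiplet(0.86, 1, linewidth = 0.035)), 8,  up),
    metabolite_spec("vldl",
      list(multiplet(0.885, 1, linewidth = 0.025),
           multiplet(1.255, 1, linewidth = 0.025)), 6, up),
    metabolite_spec("lipid_ch2",
      list(multiplet(1.285, 1, linewidth = 0.030)), 10, up),
    metabolite_spec("unsat_lipid",
      list(multiplet(5.32, 1, linewidth = 0.030)), 3,
      mult(1.00, 1.00, 1.00, 1.50)),     # interaction only
    metabolite_spec("lactate",
      list(multiplet(1.33, c(1, 1), spacing = 0.011, linewidth = 0.0045)), 16, down),
    metabolite_spec("alanine",
      list(multiplet(1.48, c(1, 1), spacing = 0.011, linewidth = 0.0045)), 4, down),
    metabolite_spec("valine",
      list(multiplet(0.99, c(1, 1), spacing = 0.010, linewidth = 0.0045),
           multiplet(1.04, c(1, 1), spacing = 0.010, linewidth = 0.0045)), 3, down),
    metabolite_spec("isoleucine",
      list(multiplet(0.94, c(1, 1), spacing = 0.010, linewidth = 0.0045),
           multiplet(1.01, c(1, 1), spacing = 0.010, linewidth = 0.0045)), 2.5, down),
    metabolite_spec("glucose",
      c(lapply(c(3.24, 3.40, 3.47, 3.54, 3.72, 3.83, 3.90),
               function(cc) multiplet(cc, 1, linewidth = 0.008)),
        list(multiplet(5.23, c(1, 1), spacing = 0.008, linewidth = 0.005))), 6,
      mult(1.00, 1.00, 1.00, 0.60))      # interaction only
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

line_profile <- function(ppm, center, fwhm, lineshape) {
  if (lineshape == "lorentzian") {
    hw <- fwhm / 2
    hw^2 / ((ppm - center)^2 + hw^2)
  } else {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(ppm - center)^2 / (2 * s^2))
  }
}

multiplet_centers <- function(m) {
  k <- length(m$intensities)
  m$center + (seq_len(k) - (k + 1) / 2) * m$spacing
}

#' Simulate one plasma CPMG-like spectrum
#'
#' Sums height-normalised Lorentzian (or Gaussian) lines for every metabolite,
#' with the metabolite amplitude set by its group multiplier times a per-sample
#' multiplicative noise term, line centres perturbed by chemical-shift jitter,
#' and additive Gaussian baseline noise. Intensities are clipped at zero.
#' Draws from the current RNG stream; [simulate_cohort()] seeds it once.
#'
#' @param specs List of [metabolite_spec()] objects.
#' @param group Group label of the sample (must index every spec's multipliers).
#' @param cfg A [cohort_config()].
#' @param sample_id Label stored on the returned spectrum.
#' @return An `nmr_spectrum` (list with `ppm`, `intensity`, `sample_id`).
#' @export
simulate_spectrum <- function(specs, group, cfg, sample_id = "sim") {
  grid <- ppm_grid(cfg)
  intensity <- numeric(length(grid))
  for (sp in specs) {
    mu <- sp$group_multipliers[[group]]
    if (is.null(mu)) stop("no multiplier for group ", group, " in ", sp$name)
    amp_noise <- if (cfg$amplitude_cv > 0) stats::rnorm(1, 0, cfg$amplitude_cv) else 0
    amp <- sp$base_amplitude * mu * max(1 + amp_noise, 0.05)
    jit <- if (cfg$shift_jitter_sd > 0) stats::rnorm(1, 0, cfg$shift_jitter_sd) else 0
    for (m in sp$multiplets) {
      centers <- multiplet_centers(m) + jit
      if (any(centers - 3 * m$linewidth < cfg$ppm_min) ||
          any(centers + 3 * m$linewidth > cfg$ppm_max))
        stop("multiplet of metabolite ", sp$name, " falls outside the ppm grid")
      for (i in seq_along(centers)) {
        intensity <- intensity +
          amp * m$intensities[i] * line_profile(grid, centers[i], m$linewidth,
                                                cfg$lineshape)
      }
    }
  }
  if (cfg$noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(grid), 0, cfg$noise_sd)
  new_spectrum(grid, pmax(intensity, 0), sample_id)
}

#' Simulate a full factorial cohort with ground truth
#'
#' Generates `4 * n_per_group` spectra (fixed order: groups as configured,
#' samples within group in index order), the matching design table and a
#' ground-truth object holding the true mean amplitude per metabolite and
#' group plus the default-grid bins overlapping each metabolite's multiplets
#' (full-width-at-half-maximum intervals). Identical seed and configuration
#' give a bit-identical cohort.
#'
#' @param cfg A [cohort_config()]; `cfg$seed` (or `seed`) controls the RNG.
#' @param specs Metabolite panel, default [metabolite_specs()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `spectra` (list of `nmr_spectrum`), `design` (data.frame:
#'   sample_id, genotype, diet, group) and `truth` (see above).
#' @export
simulate_cohort <- function(cfg = cohort_config(), specs = metabolite_specs(cfg$groups),
                            seed = cfg$seed) {
  if (anyDuplicated(cfg$groups)) stop("duplicate group labels")
  if (!is.null(seed)) set.seed(seed)
  ids <- character(0); grp <- character(0); spectra <- list()
  for (g in cfg$groups) {
    for (i in seq_len(cfg$n_per_group)) {
      id <- sprintf("%s_%02d", gsub("/", "-", g), i)
      spectra[[id]] <- simulate_spectrum(specs, g, cfg, sample_id = id)
      ids <- c(ids, id); grp <- c(grp, g)
    }
  }
  gd <- strsplit(grp, "/", fixed = TRUE)
  design <- data.frame(sample_id = ids,
                       genotype = vapply(gd, `[`, character(1), 1),
                       diet = vapply(gd, `[`, character(1), 2),
                       group = grp, stringsAsFactors = FALSE)
  list(spectra = spectra, design = design,
       truth = ground_truth(specs, cfg))
}

#' Ground truth for a simulated cohort
#'
#' True mean amplitudes (base amplitude times group multiplier) and, for the
#' default binning grid, the bin indices whose interval overlaps any line's
#' FWHM interval `[center - fwhm/2, center + fwhm/2]`.
#'
#' @param specs Metabolite panel.
#' @param cfg Cohort configuration (for grid coverage checks).
#' @param bin_width,bin_range,excluded Binning layout used to map metabolites
#'   to bin indices; defaults match [bin_cohort()].
#' @return List with `amplitudes` (metabolite x group matrix) and `bins`
#'   (named list of integer bin indices).
#' @export
ground_truth <- function(specs, cfg, bin_width = 0.02, bin_range = c(0.5, 9.0),
                         excluded = list(c(4.5, 5.0))) {
  edges <- bin_edges(bin_width, bin_range, excluded)
  amps <- t(vapply(specs, function(sp) sp$base_amplitude * sp$group_multipliers,
                   numeric(length(specs[[1]]$group_multipliers))))
  rownames(amps) <- vapply(specs, `[[`, character(1), "name")
  bins <- lapply(specs, function(sp) {
    hit <- logical(nrow(edges))
    for (m in sp$multiplets) {
      for (cc in multiplet_centers(m)) {
        lo <- cc - m$linewidth / 2; hi <- cc + m$linewidth / 2
        hit <- hit | (edges[, 1] < hi & edges[, 2] > lo)
      }
    }
    idx <- which(hit)
    if (!length(idx)) stop("metabolite ", sp$name, " maps to no bin")
    idx
  })
  names(bins) <- rownames(amps)
  list(amplitudes = amps, bins = bins)
}

#' Simulate oral glucose tolerance test curves
#'
#' @param group_means Named list (or matrix rows) of mean glucose (mmol/L) at
#'   each timepoint, one entry per group.
#' @param sd Gaussian noise SD (mmol/L).
#' @param n Animals per group.
#' @param times Sampling times in minutes, default `c(0, 5, 15, 30)`.
#' @param seed Optional seed.
#' @return Data frame: sample_id, group, one `t<min>` column per timepoint.
#' @export
simulate_ogtt <- function(group_means, sd = 0.6, n = 7, times = c(0, 5, 15, 30),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(group_means))
    group_means <- stats::setNames(split(group_means, row(group_means)),
                                   rownames(group_means))
  stopifnot(length(times) == 4L, all(diff(times) > 0))
  rows <- list()
  for (g in names(group_means)) {
    mu <- as.numeric(group_means[[g]])
    if (length(mu) != length(times)) stop("group ", g, ": wrong number of timepoints")
    if (any(mu <= 0)) stop("nonpositive mean glucose in group ", g)
    vals <- matrix(stats::rnorm(n * length(times), rep(mu, each = n), sd), nrow = n)
    vals <- pmax(vals, 0.1)
    df <- data.frame(sample_id = sprintf("%s_%02d", gsub("/", "-", g), seq_len(n)),
                     group = g, stringsAsFactors = FALSE)
    df[paste0("t", times)] <- as.data.frame(vals)
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "times") <- times
  out
}

#' Simulate a qPCR Ct table with known expression folds
#'
#' Target-gene Ct values are generated as the sample's mean reference Ct minus
#' `log2(fold)` plus noise, so the comparative-Ct method recovers the
#' configured fold exactly at zero noise.
#'
#' @param true_folds Matrix of expression folds (target genes x groups),
#'   relative to the control group (whose column should be 1).
#' @param ref_cts Named vector of mean Ct values for the reference genes.
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param n Samples per group.
#' @param seed Optional seed.
#' @return Data frame: sample_id, group, one Ct column per gene.
#' @export
simulate_ct_table <- function(true_folds, ref_cts = c(Gapdh = 18, Actb = 19),
                              noise_sd = 0, n = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(true_folds <= 0)) stop("expression folds must be positive")
  if (is.null(names(ref_cts)) || !length(ref_cts))
    stop("at least one named reference gene Ct is required")
  groups <- colnames(true_folds); genes <- rownames(true_folds)
  rows <- list()
  for (g in groups) {
    for (i in seq_len(n)) {
      ref <- ref_cts + stats::rnorm(length(ref_cts), 0, noise_sd)
      tgt <- mean(ref) - log2(true_folds[, g]) +
        stats::rnorm(length(genes), 0, noise_sd)
      row <- data.frame(sample_id = sprintf("%s_%02d", gsub("/", "-", g), i),
                        group = g, stringsAsFactors = FALSE)
      row[names(ref_cts)] <- as.list(ref)
      row[genes] <- as.list(tgt)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_genes") <- names(ref_cts)
  attr(out, "target_genes") <- genes
  out
}
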