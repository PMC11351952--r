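#' Default metabolite region table
#'
#' ppm intervals mirroring the simulator's chemical-shift table (plasma CPMG
#' reference convention), used to integrate normalized bin matrices into
#' metabolite levels. User-editable for real data.
#'
#' @return Named list of interval lists (`c(lo, hi)` in ppm).
#' @export
metabolite_regions <- function() {
  list(
    lipid_ch3   = list(c(0.80, 0.92)),
    vldl        = list(c(0.84, 0.93), c(1.22, 1.29)),
    lipid_ch2   = list(c(1.24, 1.34)),
    unsat_lipid = list(c(5.28, 5.36)),
    lactate     = list(c(1.31, 1.35)),
    alanine     = list(c(1.46, 1.50)),
    valine      = list(c(0.97, 1.06)),
    isoleucine  = list(c(0.92, 0.96), c(0.99, 1.03)),
    glucose     = list(c(3.20, 3.95), c(5.21, 5.26))
  )
}

#' Select discriminating bins by averaged VIP score
#'
#' Union over comparisons of the bins whose mean VIP exceeds the threshold in
#' at least one comparison.
#'
#' @param vips List of per-comparison mean-VIP vectors (e.g. `vip_mean` from
#'   validation reports), all of one length.
#' @param threshold VIP cutoff (default 1.5).
#' @return Sorted integer vector of selected bin indices.
#' @export
select_bins <- function(vips, threshold = 1.5) {
  if (inherits(vips, "validation_report")) vips <- list(vips)
  vv <- lapply(vips, function(v) if (inherits(v, "validation_report")) v$vip_mean else v)
  stopifnot(length(unique(vapply(vv, length, integer(1)))) == 1L)
  sort(unique(unlist(lapply(vv, function(v) which(v > threshold)))))
}

#' Integrate metabolite regions from a normalized bin matrix
#'
#' The level of a metabolite is the sum of the normalized bin integrals whose
#' bin midpoint falls inside any of the region's intervals (midpoint
#' membership avoids double counting at interval boundaries).
#'
#' @param m A `bin_matrix` in state `"normalized"`.
#' @param regions Named list of interval lists, default [metabolite_regions()].
#' @return A `metabolite_panel` in state `"level"`: `values` is a samples x
#'   metabolites matrix.
#' @export
integrate_regions <- function(m, regions = metabolite_regions()) {
  stopifnot(inherits(m, "bin_matrix"))
  if (m$state != "normalized")
    stop("integrate_regions expects a total-sum-normalized bin matrix")
  mid <- rowMeans(m$edges)
  values <- vapply(names(regions), function(nm) {
    inside <- rep(FALSE, length(mid))
    for (iv in regions[[nm]]) inside <- inside | (mid >= iv[1] & mid < iv[2])
    if (!any(inside)) stop("region ", nm, " covers no bins")
    rowSums(m$values[, inside, drop = FALSE])
  }, numeric(nrow(m$values)))
  rownames(values) <- rownames(m$values)
  structure(list(values = values, state = "level", control_group = NULL),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat("<metabolite_panel>", nrow(x$values), "samples x", ncol(x$values),
      "metabolites, state:", x$state,
      if (!is.null(x$control_group)) paste0("(control ", x$control_group, ")"),
      "\n")
  invisible(x)
}

#' Express metabolite levels as percent of the control-group mean
#'
#' @param panel A `metabolite_panel` in state `"level"`.
#' @param design Data frame with `sample_id` and `group` matching the panel
#'   rows (or a group vector of matching length).
#' @param control_group Reference group label (default `"WT/CD"`).
#' @return The panel in state `"percent"`; the control group's own mean is
#'   100 for every metabolite.
#' @export
normalize_to_control <- function(panel, design, control_group = "WT/CD") {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "level") stop("panel already normalized")
  groups <- if (is.data.frame(design)) design$group else as.character(design)
  if (length(groups) != nrow(panel$values)) stop("design does not match panel rows")
  if (!control_group %in% groups) stop("control group absent: ", control_group)
  ctrl_mean <- colMeans(panel$values[groups == control_group, , drop = FALSE])
  if (any(ctrl_mean == 0)) stop("control-group mean level is zero")
  panel$values <- 100 * sweep(panel$values, 2, ctrl_mean, `/`)
  panel$state <- "percent"
  panel$control_group <- control_group
  panel$groups <- groups
  panel
}

#' Group-by-metabolite table of mean percent levels
#'
#' The heatmap summary: rows are groups (in `group_order`), columns
#' metabolites (panel column order).
#'
#' @param panel A `metabolite_panel` in state `"percent"`.
#' @param group_order Optional row order; default order of appearance.
#' @return Numeric matrix of group means (percent of control).
#' @export
heatmap_table <- function(panel, group_order = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "percent")
    stop("heatmap_table expects a panel in percent state")
  if (is.null(group_order)) group_order <- unique(panel$groups)
  out <- matrix(NA_real_, length(group_order), ncol(panel$values),
                dimnames = list(group_order, colnames(panel$values)))
  for (g in group_order)
    out[g, ] <- colMeans(panel$values[panel$groups == g, , drop = FALSE])
  out
}
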