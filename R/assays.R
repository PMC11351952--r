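#' Normalized area under an OGTT glucose curve
#'
#' Trapezoidal area of the glucose excursion over the test period divided by
#' the basal (t = 0) glucose value, so the result is in minutes and invariant
#' to rescaling all glucose values. `method = "incremental"` instead
#' integrates the area above baseline before normalizing.
#'
#' @param glucose Glucose values (mmol/L), one per timepoint.
#' @param times Sampling times in minutes (default `c(0, 5, 15, 30)`).
#' @param method `"total"` (default) or `"incremental"` (area above baseline).
#' @return Normalized AUC in minutes.
#' @export
ogtt_auc <- function(glucose, times = c(0, 5, 15, 30),
                     method = c("total", "incremental")) {
  method <- match.arg(method)
  if (length(glucose) != length(times) || length(times) < 2)
    stop("glucose and times must match with at least 2 points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(glucose <= 0)) stop("glucose values must be positive")
  baseline <- unname(glucose[1])
  y <- if (method == "incremental") glucose - baseline else glucose
  unname(pracma::trapz(times, y)) / baseline
}

#' Normalized OGTT AUC for every animal in a table
#'
#' @param ogtt Data frame as produced by [simulate_ogtt()] (columns `t0`,
#'   `t5`, ... plus `sample_id`, `group`).
#' @inheritParams ogtt_auc
#' @return The input data frame with an `auc` column appended.
#' @export
ogtt_auc_table <- function(ogtt, method = c("total", "incremental")) {
  method <- match.arg(method)
  tcols <- grep("^t[0-9]+$", names(ogtt), value = TRUE)
  times <- as.numeric(sub("^t", "", tcols))
  o <- order(times)
  ogtt$auc <- apply(as.matrix(ogtt[tcols[o]]), 1, ogtt_auc,
                    times = times[o], method = method)
  ogtt
}

#' Comparative-Ct (delta-delta-Ct) expression folds
#'
#' For each target gene, `dCt = Ct_target - mean(Ct_reference)` per sample,
#' `ddCt = dCt - mean(dCt over control-group samples)` and
#' `fold = 2^(-ddCt)`; the control group's folds have geometric mean 1, and
#' folds are invariant to a global cycle shift of the whole table.
#'
#' @param ct Data frame with `sample_id`, `group` and one Ct column per gene
#'   (as from [simulate_ct_table()]).
#' @param control_group Reference group label.
#' @param reference_genes,target_genes Gene column names; defaults taken from
#'   the table's attributes when present.
#' @return Data frame: `sample_id`, `group`, one fold column per target gene.
#' @export
ddct_folds <- function(ct, control_group,
                       reference_genes = attr(ct, "reference_genes"),
                       target_genes = attr(ct, "target_genes")) {
  if (is.null(reference_genes) || !length(reference_genes))
    stop("reference genes must be given")
  if (is.null(target_genes) || !length(target_genes))
    stop("target genes must be given")
  missing_ref <- setdiff(reference_genes, names(ct))
  if (length(missing_ref))
    stop("missing reference gene column: ", paste(missing_ref, collapse = ", "))
  if (anyNA(ct[reference_genes]))
    stop("missing reference Ct value in sample ",
         paste(ct$sample_id[!stats::complete.cases(ct[reference_genes])],
               collapse = ", "))
  if (!control_group %in% ct$group) stop("control group absent: ", control_group)
  ref_mean <- rowMeans(as.matrix(ct[reference_genes]))
  out <- ct[c("sample_id", "group")]
  ctrl <- ct$group == control_group
  for (g in target_genes) {
    dct <- ct[[g]] - ref_mean
    ddct <- dct - mean(dct[ctrl])
    out[[g]] <- 2^(-ddct)
  }
  out
}
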