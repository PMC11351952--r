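# Plain-text exchange formats: spectra as 2-column TSV (ppm, intensity),
# tables as TSV with named columns, bin matrices as TSV plus a JSON sidecar
# carrying edges/state/exclusions. Numbers are written with full double
# precision so write -> read round trips are bit-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a spectrum to a two-column delimited text file
#'
#' @param s An `nmr_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  utils::write.table(
    data.frame(ppm = fmt_num(s$ppm), intensity = fmt_num(s$intensity)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path Input file path.
#' @param sample_id Sample label (default: file name without extension).
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  for (col in c("ppm", "intensity"))
    if (!col %in% names(df))
      stop("malformed spectrum file ", path, ": missing column '", col,
           "' (line 1)")
  new_spectrum(df$ppm, df$intensity, sample_id)
}

#' Write a design (or any sample) table as TSV
#'
#' @param design Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design table, validating the required columns
#'
#' Unknown extra columns are preserved.
#'
#' @param path Input file path.
#' @param required Column names that must be present.
#' @return Data frame.
#' @export
read_design <- function(path, required = c("sample_id", "genotype", "diet", "group")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("design file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), " (line 1)")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' Write a bin matrix as TSV plus JSON sidecar
#'
#' The sidecar (`<path>.json`) stores bin edges, processing state, excluded
#' regions and bin width.
#'
#' @param m A `bin_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(m, path) {
  stopifnot(inherits(m, "bin_matrix"))
  df <- as.data.frame(apply(m$values, 2, fmt_num))
  df <- cbind(sample_id = rownames(m$values), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(schema = "metabocv/bin_matrix/1", state = m$state,
               width = m$width, edges = unname(apply(m$edges, 1, c, simplify = FALSE)),
               excluded = lapply(m$excluded, as.numeric))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bin matrix written by [write_bin_matrix()]
#'
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return A `bin_matrix`.
#' @export
read_bin_matrix <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("malformed bin matrix ", path, ": missing column 'sample_id' (line 1)")
  values <- as.matrix(df[setdiff(names(df), "sample_id")])
  storage.mode(values) <- "double"
  rownames(values) <- df$sample_id
  edges <- if (is.matrix(meta$edges)) meta$edges else do.call(rbind, meta$edges)
  colnames(edges) <- c("lo", "hi")
  excluded <- if (is.matrix(meta$excluded)) {
    lapply(seq_len(nrow(meta$excluded)), function(i) meta$excluded[i, ])
  } else as.list(meta$excluded)
  new_bin_matrix(values, edges, state = meta$state,
                 excluded = excluded, width = meta$width)
}

#' Write an analysis report as JSON
#'
#' @param report A list (e.g. the result of [run_pipeline()]'s `report`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
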