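#' Read an expression dataset from a series-matrix-style TSV
#'
#' The dialect mirrors a simplified GEO series matrix: an optional
#' `!Sample_group` line (tab-separated, one `case`/`control` label per
#' sample, aligned with the sample columns), then a header row
#' (`gene_id` followed by sample ids), then one row per gene/probe.
#' When the file has no `!Sample_group` line, `groups` must name a sidecar
#' two-column TSV (`sample`, `group`).
#'
#' @param path Path to the expression TSV.
#' @param dataset_id Dataset identifier; default: file name without
#'   extension.
#' @param groups Optional path to a sample-to-group sidecar TSV.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL, groups = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  if (is.null(dataset_id))
    dataset_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE, n = 1)
  has_group_line <- length(lines) == 1 && startsWith(lines[1], "!Sample_group")
  skip <- if (has_group_line) 1 else 0
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (has_group_line) {
    g <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  } else {
    if (is.null(groups))
      stop("no !Sample_group line; supply a sample-to-group sidecar TSV",
           call. = FALSE)
    side <- utils::read.delim(groups, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "group") %in% names(side)))
    g <- side$group[match(colnames(m), side$sample)]
    if (any(is.na(g)))
      stop("sidecar is missing group labels for some samples", call. = FALSE)
  }
  expression_dataset(dataset_id, m, g)
}

#' Write an expression dataset as a series-matrix-style TSV
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @param digits Significant digits used for the fixed-precision text
#'   serialization; default 10 (full reproducibility of round trips at the
#'   precision written).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, digits = 10) {
  stopifnot(inherits(dataset, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("!Sample_group", dataset$groups), collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(dataset$matrix)), collapse = "\t"),
             con)
  body <- apply(dataset$matrix, 1, function(r)
    paste(signif(r, digits), collapse = "\t"))
  writeLines(paste(rownames(dataset$matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Write a mega-analysis result table as TSV
#'
#' @param results A `mega_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mega_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a QQ report as JSON
#'
#' @param report A `qq_report` from [qq_check()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qq_report <- function(report, path) {
  stopifnot(inherits(report, "qq_report"))
  jsonlite::write_json(
    list(dataset_id = report$dataset_id,
         deviation = report$deviation,
         systematic_bias = report$systematic_bias,
         n_genes = length(report$statistic),
         statistic = report$statistic,
         theoretical = report$theoretical),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
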