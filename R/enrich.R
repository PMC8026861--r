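#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-delimited — set id, description, then
#' member gene symbols. Members are upper-cased and deduplicated within a
#' line.
#'
#' @param path Path to a GMT file.
#' @return A list of gene sets; each element is a list with `set_id`, `name`
#'   and `members` (character vector), named by `set_id`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated columns",
           call. = FALSE)
    members <- unique(toupper(trimws(fields[-(1:2)])))
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("GMT line ", i, " has no gene members", call. = FALSE)
    sets[[i]] <- list(set_id = fields[1], name = fields[2], members = members)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  sets
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis against gene-set collections
#'
#' Tests a query gene set against each collection set with a one-sided Fisher
#' exact test (hypergeometric upper tail) over a background universe, adjusts
#' across sets with Benjamini-Hochberg, and flags the sets passing the
#' reporting criteria: `q <= q_cut`, background-restricted set size
#' `<= set_size_max`, and overlap percentage (overlap / set size)
#' `>= overlap_min_percent`.
#'
#' @param query Character vector of query gene symbols.
#' @param sets Gene-set list as returned by [read_gmt()].
#' @param background Character vector of background genes; default: the union
#'   of all set members. Query genes outside the background are dropped with
#'   a warning; set members outside the background do not count.
#' @param q_cut FDR threshold; default 0.005.
#' @param set_size_max Maximum allowed (background-restricted) set size;
#'   default 1000.
#' @param overlap_min_percent Minimum overlap percentage; default 2.
#' @return A data frame sorted by p ascending with columns `set_id`, `name`,
#'   `overlap_count`, `set_size`, `overlap_percent`, `p`, `q`, `passed` and a
#'   comma-separated `overlap_genes` column.
#' @export
enrich <- function(query, sets, background = NULL, q_cut = 0.005,
                   set_size_max = 1000, overlap_min_percent = 2) {
  query <- unique(toupper(query))
  if (length(query) == 0) stop("query gene set is empty", call. = FALSE)
  if (is.null(background))
    background <- unique(toupper(unlist(lapply(sets, `[[`, "members"))))
  else background <- unique(toupper(background))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query <- intersect(query, background)
    if (length(query) == 0)
      stop("no query gene is in the background", call. = FALSE)
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(toupper(s$members), background)
    if (length(members) == 0) {
      warning("set ", s$set_id, " has no member in the background; skipped",
              call. = FALSE)
      return(NULL)
    }
    ov <- intersect(query, members)
    m <- length(members)
    # upper tail P(X >= |ov|) for X ~ Hypergeom(bg, set m, draws n_q)
    p <- stats::phyper(length(ov) - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    data.frame(set_id = s$set_id, name = s$name,
               overlap_count = length(ov), set_size = m,
               overlap_percent = 100 * length(ov) / m,
               p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no gene set overlaps the background", call. = FALSE)
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$passed <- out$q <= q_cut & out$set_size <= set_size_max &
    out$overlap_percent >= overlap_min_percent
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_id", "name", "overlap_count", "set_size", "overlap_percent",
          "p", "q", "passed", "overlap_genes")]
}
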