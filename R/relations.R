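#' Read a signed relation table
#'
#' Reads a tab-delimited table of signed, literature-derived relations between
#' entities (diseases, genes, small molecules). Each row is one directed
#' assertion `subject -> object` with an effect polarity and the number of
#' supporting references behind it.
#'
#' Required columns are `subject`, `object`, `polarity` and `ref_count`;
#' `subject_kind`, `object_kind`, `relation_class` and `sentences` are optional
#' and filled with defaults when absent. Entity identifiers are matched
#' case-insensitively and stored upper-case. Polarity tokens other than
#' `positive`/`negative` (any case) are preserved as `"unknown"` so that
#' [qc_filter()] can remove them explicitly.
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @return A `data.frame` of class `relation_table` with columns `subject`,
#'   `subject_kind`, `object`, `object_kind`, `polarity`, `relation_class`,
#'   `ref_count` and `sentences`.
#' @seealso [qc_filter()], [account_gene_sets()], [protective_networks()]
#' @export
read_relations <- function(path) {
  if (!file.exists(path)) {
    stop("relation table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = TRUE,
                           colClasses = "character")
  required <- c("subject", "object", "polarity", "ref_count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("relation table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("relation table ", path, " has a header but no data rows",
            call. = FALSE)
  }
  as_relation_table(raw)
}

#' Build a relation table from a data frame
#'
#' Normalises a data frame of signed relations into the canonical
#' `relation_table` layout used across the package: identifiers upper-cased,
#' polarity tokens canonicalised to `positive`/`negative`/`unknown`,
#' `ref_count` integer, optional columns defaulted.
#'
#' @param df A data frame with at least `subject`, `object`, `polarity`,
#'   `ref_count`.
#' @return A `relation_table` data frame.
#' @export
as_relation_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("subject", "object", "polarity", "ref_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  pol <- tolower(trimws(as.character(df$polarity)))
  pol[!(pol %in% c("positive", "negative"))] <- "unknown"
  out <- data.frame(
    subject = toupper(trimws(as.character(df$subject))),
    subject_kind = if ("subject_kind" %in% names(df))
      tolower(trimws(as.character(df$subject_kind))) else rep("gene", n),
    object = toupper(trimws(as.character(df$object))),
    object_kind = if ("object_kind" %in% names(df))
      tolower(trimws(as.character(df$object_kind))) else rep("gene", n),
    polarity = pol,
    relation_class = if ("relation_class" %in% names(df))
      as.character(df$relation_class) else rep("regulation", n),
    ref_count = as.integer(round(as.numeric(df$ref_count))),
    sentences = if ("sentences" %in% names(df))
      as.character(df$sentences) else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$ref_count)) || any(out$ref_count < 0)) {
    stop("ref_count must be a non-negative integer for every row",
         call. = FALSE)
  }
  if (any(out$subject == out$object)) {
    stop("self-relations (subject == object) are not allowed", call. = FALSE)
  }
  class(out) <- c("relation_table", "data.frame")
  out
}

#' Quality-control filter for signed relations
#'
#' Keeps only relations backed by at least `min_refs` supporting references and
#' with a defined effect polarity (`positive` or `negative`). Rows with unknown
#' or unclear polarity are removed regardless of evidence volume. Input order
#' is preserved, and the operation is idempotent.
#'
#' @param relations A `relation_table` (see [read_relations()]).
#' @param min_refs Minimum number of supporting references; default 3.
#' @return The filtered `relation_table` (possibly empty).
#' @export
qc_filter <- function(relations, min_refs = 3) {
  relations <- as_relation_table(relations)
  stopifnot(length(min_refs) == 1, min_refs >= 1)
  keep <- relations$ref_count >= min_refs &
    relations$polarity %in% c("positive", "negative")
  out <- relations[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relation_table", "data.frame")
  out
}

# Collapse duplicate (subject, object) rows to a single signed edge.
# Evidence is summed per polarity; the polarity with the larger summed
# ref_count wins; an exact tie yields polarity "unknown" (which downstream
# consumers treat as undefined and drop).
aggregate_edges <- function(relations) {
  relations <- as_relation_table(relations)
  if (nrow(relations) == 0) return(relations)
  key <- paste(relations$subject, relations$object, sep = "\r")
  pieces <- split(seq_len(nrow(relations)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- relations[idx, , drop = FALSE]
    pos <- sum(sub$ref_count[sub$polarity == "positive"])
    neg <- sum(sub$ref_count[sub$polarity == "negative"])
    polarity <- if (pos > neg) "positive" else if (neg > pos) "negative" else "unknown"
    data.frame(
      subject = sub$subject[1], subject_kind = sub$subject_kind[1],
      object = sub$object[1], object_kind = sub$object_kind[1],
      polarity = polarity,
      relation_class = sub$relation_class[1],
      ref_count = as.integer(pos + neg),
      sentences = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$object), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relation_table", "data.frame")
  out
}

#' Signed network from a relation table
#'
#' Aggregates a relation table to at most one signed edge per ordered
#' `(subject, object)` pair (summed evidence, majority polarity; exact
#' polarity ties are undefined and dropped) and wraps the result as a
#' directed signed network.
#'
#' @param relations A `relation_table`, typically already passed through
#'   [qc_filter()].
#' @return An object of class `signed_network`: a list with a `nodes` data
#'   frame (`id`, `kind`) and an `edges` data frame (`subject`, `object`,
#'   `polarity` coded +1/-1, `ref_count`).
#' @export
signed_network <- function(relations) {
  agg <- aggregate_edges(relations)
  agg <- agg[agg$polarity %in% c("positive", "negative"), , drop = FALSE]
  edges <- data.frame(
    subject = agg$subject,
    object = agg$object,
    polarity = as.integer(ifelse(agg$polarity == "positive", 1L, -1L)),
    ref_count = agg$ref_count,
    stringsAsFactors = FALSE
  )
  ids <- unique(c(agg$subject, agg$object))
  kind <- character(length(ids))
  names(kind) <- ids
  kind[agg$subject] <- agg$subject_kind
  kind[agg$object] <- agg$object_kind
  nodes <- data.frame(id = ids, kind = unname(kind[ids]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$polarity == 1), "positive /",
      sum(x$edges$polarity == -1), "negative )\n")
  invisible(x)
}

#' Export a signed network as an edge-list TSV
#'
#' @param network A `signed_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(network, path) {
  stopifnot(inherits(network, "signed_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a signed network to an igraph object
#'
#' Edge polarity is carried as the numeric edge attribute `polarity`
#' (+1/-1), node kind as the vertex attribute `kind` — attributes that
#' survive a GraphML export via [igraph::write_graph()].
#'
#' @param network A `signed_network`.
#' @return A directed [igraph::igraph] graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  igraph::graph_from_data_frame(
    d = network$edges[, c("subject", "object", "polarity", "ref_count")],
    directed = TRUE,
    vertices = network$nodes
  )
}

#' Set accounting for two diseases over a signed relation table
#'
#' Computes, from QC-passed relations, the genes downstream of `disease_a`
#' (its targets, with the disease-to-gene polarity), the genes upstream of
#' `disease_b` (its regulators, with the gene-to-disease polarity), their
#' intersection, and the targets of `disease_a` not implicated in `disease_b`.
#' Only entities of kind `gene` enter the accounting. Edges are aggregated to
#' one polarity per pair first; pairs whose evidence ties between polarities
#' are undefined and excluded.
#'
#' @param relations A QC-filtered `relation_table`.
#' @param disease_a Identifier of the upstream disease (case-insensitive).
#' @param disease_b Identifier of the downstream disease.
#' @return An object of class `gene_sets_accounting`: a list with data frames
#'   `targets_a` (`gene`, `polarity`) and `regulators_b` (`gene`, `polarity`),
#'   character vectors `shared` and `a_only`, and a named integer `counts`.
#' @export
account_gene_sets <- function(relations, disease_a, disease_b) {
  agg <- aggregate_edges(relations)
  agg <- agg[agg$polarity %in% c("positive", "negative"), , drop = FALSE]
  disease_a <- toupper(disease_a)
  disease_b <- toupper(disease_b)
  if (!(disease_a %in% c(agg$subject, agg$object))) {
    warning("disease '", disease_a, "' not found in the relation table",
            call. = FALSE)
  }
  if (!(disease_b %in% c(agg$subject, agg$object))) {
    warning("disease '", disease_b, "' not found in the relation table",
            call. = FALSE)
  }
  ta <- agg[agg$subject == disease_a & agg$object_kind == "gene", , drop = FALSE]
  rb <- agg[agg$object == disease_b & agg$subject_kind == "gene", , drop = FALSE]
  targets_a <- data.frame(gene = ta$object, polarity = ta$polarity,
                          stringsAsFactors = FALSE)
  regulators_b <- data.frame(gene = rb$subject, polarity = rb$polarity,
                             stringsAsFactors = FALSE)
  shared <- sort(intersect(targets_a$gene, regulators_b$gene))
  a_only <- sort(setdiff(targets_a$gene, shared))
  counts <- c(targets_a = nrow(targets_a),
              regulators_b = nrow(regulators_b),
              shared = length(shared),
              a_only = length(a_only))
  structure(list(disease_a = disease_a, disease_b = disease_b,
                 targets_a = targets_a, regulators_b = regulators_b,
                 shared = shared, a_only = a_only, counts = counts),
            class = "gene_sets_accounting")
}

#' @export
print.gene_sets_accounting <- function(x, ...) {
  cat("Gene-set accounting for", x$disease_a, "->", x$disease_b, "\n")
  cat("  targets of", paste0(x$disease_a, ":"), x$counts[["targets_a"]], "\n")
  cat("  regulators of", paste0(x$disease_b, ":"), x$counts[["regulators_b"]], "\n")
  cat("  shared:", x$counts[["shared"]],
      " |  ", x$disease_a, "-only:", x$counts[["a_only"]], "\n")
  invisible(x)
}

#' Protective disease-to-disease networks
#'
#' Scans a QC-filtered relation table for the two protective sign patterns
#' linking `disease_a` to `disease_b` through a gene g:
#'
#' * inhibited promoters: `disease_a -| g` (negative) and `g -> disease_b`
#'   (positive) — genes promoting the downstream disease that the upstream
#'   disease suppresses;
#' * activated inhibitors: `disease_a -> g` (positive) and `g -| disease_b`
#'   (negative) — downstream-disease inhibitors the upstream disease induces.
#'
#' Each pattern is returned as a [signed_network()] containing the two
#' diseases, the qualifying genes and the qualifying edges.
#'
#' @inheritParams account_gene_sets
#' @return A list with elements `inhibited_promoters` and
#'   `activated_inhibitors`, each a `signed_network`, plus `genes`, a list of
#'   the two gene vectors.
#' @export
protective_networks <- function(relations, disease_a, disease_b) {
  agg <- aggregate_edges(relations)
  agg <- agg[agg$polarity %in% c("positive", "negative"), , drop = FALSE]
  disease_a <- toupper(disease_a)
  disease_b <- toupper(disease_b)
  a_edges <- agg[agg$subject == disease_a & agg$object_kind == "gene", , drop = FALSE]
  b_edges <- agg[agg$object == disease_b & agg$subject_kind == "gene", , drop = FALSE]
  pick <- function(pol_a, pol_b) {
    genes <- sort(intersect(a_edges$object[a_edges$polarity == pol_a],
                            b_edges$subject[b_edges$polarity == pol_b]))
    rows <- rbind(
      a_edges[a_edges$object %in% genes & a_edges$polarity == pol_a, , drop = FALSE],
      b_edges[b_edges$subject %in% genes & b_edges$polarity == pol_b, , drop = FALSE]
    )
    class(rows) <- c("relation_table", "data.frame")
    list(genes = genes, network = signed_network(rows))
  }
  inh <- pick("negative", "positive")
  act <- pick("positive", "negative")
  list(
    inhibited_promoters = inh$network,
    activated_inhibitors = act$network,
    genes = list(inhibited_promoters = inh$genes,
                 activated_inhibitors = act$genes)
  )
}
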