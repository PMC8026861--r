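#' Enumerate signed shortest paths between two entities
#'
#' Finds all directed paths of minimum hop count from `source` to `target`
#' in a signed network, composes each path's net regulatory sign as the
#' product of its edge polarities, and returns them in deterministic
#' (lexicographic by node sequence) order. Paths are simple; hop count is the
#' length metric (edges are unweighted).
#'
#' @param network A [signed_network()].
#' @param source,target Entity identifiers present in the network
#'   (case-insensitive); must differ.
#' @param max_paths Maximum number of paths returned; default 100.
#' @return A data frame of class `signed_paths` with one row per path:
#'   list-columns `nodes` and `polarities`, plus `length` and `net_sign`.
#'   Zero rows when no path exists.
#' @export
shortest_signed_paths <- function(network, source, target, max_paths = 100) {
  stopifnot(inherits(network, "signed_network"))
  source <- toupper(source)
  target <- toupper(target)
  if (source == target)
    stop("source and target must differ", call. = FALSE)
  if (!(source %in% network$nodes$id))
    stop("source '", source, "' not in network", call. = FALSE)
  if (!(target %in% network$nodes$id))
    stop("target '", target, "' not in network", call. = FALSE)
  empty <- structure(
    data.frame(length = integer(), net_sign = integer()),
    class = c("signed_paths", "data.frame"))
  empty$nodes <- list()
  empty$polarities <- list()
  if (nrow(network$edges) == 0) return(empty)
  g <- as_igraph(network)
  asp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = target, mode = "out"))
  if (length(asp$res) == 0) return(empty)
  node_seqs <- lapply(asp$res, function(v) igraph::as_ids(v))
  keys <- vapply(node_seqs, paste, character(1), collapse = "\r")
  node_seqs <- node_seqs[order(keys)]
  if (length(node_seqs) > max_paths)
    node_seqs <- node_seqs[seq_len(max_paths)]
  pol_lookup <- stats::setNames(
    network$edges$polarity,
    paste(network$edges$subject, network$edges$object, sep = "\r"))
  rows <- lapply(node_seqs, function(ns) {
    pk <- paste(ns[-length(ns)], ns[-1], sep = "\r")
    pols <- unname(pol_lookup[pk])
    data.frame(length = length(ns) - 1L,
               net_sign = as.integer(prod(pols)))
  })
  out <- do.call(rbind, rows)
  out$nodes <- node_seqs
  out$polarities <- lapply(node_seqs, function(ns) {
    unname(pol_lookup[paste(ns[-length(ns)], ns[-1], sep = "\r")])
  })
  out <- out[, c("nodes", "polarities", "length", "net_sign")]
  rownames(out) <- NULL
  class(out) <- c("signed_paths", "data.frame")
  out
}

#' @export
print.signed_paths <- function(x, ...) {
  cat(nrow(x), "shortest path(s)\n")
  for (i in seq_len(nrow(x))) {
    ns <- x$nodes[[i]]
    pols <- x$polarities[[i]]
    arrows <- ifelse(pols == 1, " ->(+) ", " -|(-) ")
    cat("  ", ns[1], paste0(arrows, ns[-1], collapse = ""),
        "  [net ", ifelse(x$net_sign[i] == 1, "+", "-"), "]\n", sep = "")
  }
  invisible(x)
}

#' Classify path intermediates by their direct role for a disease
#'
#' Labels every intermediate node of a path set as a `promoter` (direct
#' positive edge into the disease), `inhibitor` (direct negative edge) or
#' `indirect` (no direct edge), using the same relation set the paths were
#' computed on. The overall verdict is `"mixed"` when both promoters and
#' inhibitors occur, otherwise `"promoter"`, `"inhibitor"` or `"indirect"`.
#'
#' @param paths A `signed_paths` object from [shortest_signed_paths()].
#' @param relations The relation table (QC-filtered) the paths came from.
#' @param disease Disease identifier the roles refer to.
#' @return A list with `roles`, a data frame (`node`, `role`), and `verdict`.
#' @export
classify_intermediates <- function(paths, relations, disease) {
  stopifnot(inherits(paths, "signed_paths"))
  disease <- toupper(disease)
  agg <- aggregate_edges(relations)
  agg <- agg[agg$polarity %in% c("positive", "negative"), , drop = FALSE]
  inter <- unique(unlist(lapply(paths$nodes, function(ns) {
    if (length(ns) <= 2) character(0) else ns[-c(1, length(ns))]
  })))
  inter <- sort(inter)
  role <- vapply(inter, function(node) {
    hit <- agg[agg$subject == node & agg$object == disease, , drop = FALSE]
    if (nrow(hit) == 0) "indirect"
    else if (hit$polarity[1] == "positive") "promoter"
    else "inhibitor"
  }, character(1))
  verdict <- if ("promoter" %in% role && "inhibitor" %in% role) "mixed"
  else if ("promoter" %in% role) "promoter"
  else if ("inhibitor" %in% role) "inhibitor"
  else "indirect"
  list(roles = data.frame(node = inter, role = unname(role),
                          stringsAsFactors = FALSE),
       verdict = verdict)
}

#' Write signed paths as a TSV
#'
#' One row per path: pipe-separated node sequence, pipe-separated edge
#' polarities, hop count and the composed net sign.
#'
#' @param paths A `signed_paths` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signed_paths <- function(paths, path) {
  stopifnot(inherits(paths, "signed_paths"))
  flat <- data.frame(
    nodes = vapply(paths$nodes, paste, character(1), collapse = "|"),
    polarities = vapply(paths$polarities, paste, character(1), collapse = "|"),
    length = paths$length,
    net_sign = paths$net_sign,
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signed network in DOT format
#'
#' Positive edges are drawn as arrows, negative edges as tee-headed arrows,
#' for visualisation with Graphviz.
#'
#' @param network A `signed_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(network, path) {
  stopifnot(inherits(network, "signed_network"))
  quote_id <- function(x) paste0('"', x, '"')
  lines <- c("digraph signed_network {")
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    style <- if (e$polarity == 1) "[arrowhead=normal, color=black]"
             else "[arrowhead=tee, color=red]"
    lines <- c(lines, paste0("  ", quote_id(e$subject), " -> ",
                             quote_id(e$object), " ", style, ";"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
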