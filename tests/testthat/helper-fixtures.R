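# Programmatic fixtures shared across test files.

# Random conflict-free signed relation table around two diseases.
random_relation_df <- function(n_genes = 20, seed = 1,
                               a = "OBESITY", b = "MI") {
  set.seed(seed)
  genes <- sprintf("RG%03d", seq_len(n_genes))
  rows <- list()
  for (g in genes) {
    if (stats::runif(1) < 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        subject = a, subject_kind = "disease", object = g,
        object_kind = "gene",
        polarity = sample(c("positive", "negative"), 1),
        relation_class = "regulation",
        ref_count = sample(3:15, 1), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        subject = g, subject_kind = "gene", object = b,
        object_kind = "disease",
        polarity = sample(c("positive", "negative"), 1),
        relation_class = "regulation",
        ref_count = sample(3:15, 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Random directed signed graph as a relation-style edge table.
random_graph_df <- function(n_nodes, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  rows <- list()
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i != j && stats::runif(1) < p_edge) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = nodes[i], subject_kind = "gene",
        object = nodes[j], object_kind = "gene",
        polarity = sample(c("positive", "negative"), 1),
        relation_class = "regulation", ref_count = sample(3:9, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# Tiny two-group expression dataset with chosen per-gene shifts.
tiny_dataset <- function(id = "T1", n_genes = 10, n_case = 5, n_control = 5,
                         shift = 0, sd = 1, seed = 1, baseline = 8) {
  set.seed(seed)
  shift <- rep_len(shift, n_genes)
  m <- matrix(stats::rnorm(n_genes * (n_case + n_control), baseline, sd),
              n_genes, n_case + n_control)
  m[, seq_len(n_case)] <- m[, seq_len(n_case)] + shift
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_dataset(id, m, c(rep("case", n_case), rep("control", n_control)))
}
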