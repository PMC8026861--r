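#' Case/control design of the seven published MI array studies
#'
#' The default multi-study design used by the expression simulator: seven
#' case-control array studies with control/case sizes 4/34, 7/17, 50/49,
#' 7/10, 48/49, 21/31 and 14/84 — the sample-size structure of the published
#' myocardial-infarction mega-analysis designs this package emulates.
#'
#' @return A data frame with columns `dataset_id`, `n_control`, `n_case`.
#' @export
reference_designs <- function() {
  data.frame(
    dataset_id = paste0("SYN", 1:7),
    n_control = c(4L, 7L, 50L, 7L, 48L, 21L, 14L),
    n_case = c(34L, 17L, 49L, 10L, 49L, 31L, 84L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for multi-study expression data
#'
#' @param dataset_designs Data frame with `dataset_id`, `n_control`, `n_case`;
#'   default [reference_designs()].
#' @param n_genes Number of genes.
#' @param planted_lfc Per-gene true pooled log2 fold-change; recycled to
#'   `n_genes`.
#' @param tau2 Between-study variance of the per-dataset true effect
#'   (log2 units squared); >= 0. May be per-gene (recycled).
#' @param noise_sd Within-group residual standard deviation, log2 units.
#' @param baseline_mean Log2 expression baseline of the controls.
#' @param seed Integer seed; every simulation from the same config is
#'   byte-identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(dataset_designs = reference_designs(), n_genes = 200,
                       planted_lfc = 0, tau2 = 0, noise_sd = 1,
                       baseline_mean = 8, seed = 1) {
  problems <- character(0)
  if (!is.data.frame(dataset_designs) ||
      !all(c("dataset_id", "n_control", "n_case") %in% names(dataset_designs)) ||
      nrow(dataset_designs) < 1)
    problems <- c(problems, "dataset_designs must have dataset_id, n_control, n_case")
  else if (any(dataset_designs$n_control < 1) || any(dataset_designs$n_case < 1))
    problems <- c(problems, "all group sizes must be positive")
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    problems <- c(problems, "n_genes must be a positive integer")
  if (any(tau2 < 0)) problems <- c(problems, "tau2 must be >= 0")
  if (!is.numeric(noise_sd) || any(noise_sd <= 0))
    problems <- c(problems, "noise_sd must be > 0")
  if (!is.numeric(seed) || length(seed) != 1)
    problems <- c(problems, "seed must be a single integer")
  if (length(problems) > 0)
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(list(
    dataset_designs = dataset_designs,
    n_genes = as.integer(n_genes),
    planted_lfc = rep_len(planted_lfc, n_genes),
    tau2 = rep_len(tau2, n_genes),
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate multi-study case-control expression data with planted truth
#'
#' For each gene g and dataset i, the dataset-level true effect is drawn as
#' `theta_gi ~ Normal(planted_lfc_g, tau2_g)`; control samples are
#' `Normal(baseline_mean, noise_sd^2)` and case samples
#' `Normal(baseline_mean + theta_gi, noise_sd^2)`, all on the log2 scale.
#' With `tau2 = 0` every dataset shares the gene's planted effect (the
#' fixed-effect regime); `tau2 > 0` plants genuine between-study
#' heterogeneity (the random-effects regime).
#'
#' @param config A [sim_config()].
#' @return A list with `datasets` (list of [expression_dataset()]) and
#'   `truth`, itself a list with `planted` (data frame `gene`,
#'   `planted_lfc`, `tau2`) and `realized` (genes x datasets matrix of the
#'   drawn `theta_gi`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  designs <- config$dataset_designs
  nd <- nrow(designs)
  realized <- base::matrix(NA_real_, config$n_genes, nd,
                           dimnames = list(genes, designs$dataset_id))
  datasets <- vector("list", nd)
  for (i in seq_len(nd)) {
    nc <- designs$n_case[i]
    nk <- designs$n_control[i]
    theta <- stats::rnorm(config$n_genes, config$planted_lfc,
                          sqrt(config$tau2))
    realized[, i] <- theta
    ctrl <- base::matrix(stats::rnorm(config$n_genes * nk,
                                      config$baseline_mean, config$noise_sd),
                         config$n_genes, nk)
    case <- base::matrix(stats::rnorm(config$n_genes * nc,
                                      config$baseline_mean, config$noise_sd),
                         config$n_genes, nc) + theta
    m <- cbind(case, ctrl)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("%s_case_%02d", designs$dataset_id[i], 1:nc),
                     sprintf("%s_ctrl_%02d", designs$dataset_id[i], 1:nk))
    datasets[[i]] <- expression_dataset(
      designs$dataset_id[i], m,
      c(rep("case", nc), rep("control", nk)))
  }
  names(datasets) <- designs$dataset_id
  list(datasets = datasets,
       truth = list(planted = data.frame(gene = genes,
                                         planted_lfc = config$planted_lfc,
                                         tau2 = config$tau2,
                                         stringsAsFactors = FALSE),
                    realized = realized))
}

#' Simulate a signed disease-gene relation table with planted set structure
#'
#' Generates a literature-style relation table linking an upstream disease
#' (`disease_a`) and a downstream disease (`disease_b`) through genes, with
#' the gene-set structure planted exactly: `n_a_only` genes targeted only by
#' `disease_a`, `n_b_only` genes regulating only `disease_b`, and shared
#' genes in the four sign patterns given by `shared_patterns` (named counts:
#' `inhibited_promoter` = a-|g, g->b; `activated_inhibitor` = a->g, g-|b;
#' `concordant_positive` = a->g, g->b; `concordant_negative` = a-|g, g-|b).
#' Optionally adds noise rows that quality control must remove: relations
#' with fewer than 3 references and relations with unknown polarity.
#'
#' @param disease_a,disease_b Disease identifiers.
#' @param n_a_only,n_b_only Gene counts for the unshared groups.
#' @param shared_patterns Named integer vector of the four pattern counts.
#' @param n_below_refs Number of extra sub-threshold rows (ref_count < 3).
#' @param n_unknown_polarity Number of extra unknown-polarity rows.
#' @param seed Integer seed.
#' @return A list with `relations` (a `relation_table`, rows shuffled) and
#'   `truth` (data frame `gene`, `group` with the planted pattern of every
#'   gene).
#' @export
simulate_relations <- function(disease_a = "OBESITY", disease_b = "MI",
                               n_a_only = 472, n_b_only = 130,
                               shared_patterns = c(inhibited_promoter = 11,
                                                   activated_inhibitor = 0,
                                                   concordant_positive = 45,
                                                   concordant_negative = 45),
                               n_below_refs = 20, n_unknown_polarity = 20,
                               seed = 1) {
  stopifnot(all(c("inhibited_promoter", "activated_inhibitor",
                  "concordant_positive", "concordant_negative") %in%
                  names(shared_patterns)))
  set.seed(seed)
  disease_a <- toupper(disease_a)
  disease_b <- toupper(disease_b)
  n_shared <- sum(shared_patterns)
  total <- n_a_only + n_b_only + n_shared
  genes <- sprintf("GENE%04d", seq_len(total))
  group <- c(rep("a_only", n_a_only), rep("b_only", n_b_only),
             rep(names(shared_patterns), shared_patterns))
  refs <- function(n) sample(3:25, n, replace = TRUE)
  rel <- function(subject, object, polarity, skind, okind, n) {
    if (n == 0) return(NULL)
    data.frame(subject = subject, subject_kind = skind, object = object,
               object_kind = okind, polarity = polarity,
               relation_class = "regulation", ref_count = refs(n),
               sentences = NA_character_, stringsAsFactors = FALSE)
  }
  a_pol <- character(total)   # polarity of disease_a -> gene
  b_pol <- character(total)   # polarity of gene -> disease_b
  a_pol[group == "a_only"] <- sample(c("positive", "negative"),
                                     n_a_only, replace = TRUE)
  b_pol[group == "b_only"] <- sample(c("positive", "negative"),
                                     n_b_only, replace = TRUE)
  a_pol[group == "inhibited_promoter"] <- "negative"
  b_pol[group == "inhibited_promoter"] <- "positive"
  a_pol[group == "activated_inhibitor"] <- "positive"
  b_pol[group == "activated_inhibitor"] <- "negative"
  a_pol[group == "concordant_positive"] <- "positive"
  b_pol[group == "concordant_positive"] <- "positive"
  a_pol[group == "concordant_negative"] <- "negative"
  b_pol[group == "concordant_negative"] <- "negative"
  has_a <- a_pol != ""
  has_b <- b_pol != ""
  rows <- list(
    rel(disease_a, genes[has_a], a_pol[has_a], "disease", "gene", sum(has_a)),
    rel(genes[has_b], disease_b, b_pol[has_b], "gene", "disease", sum(has_b))
  )
  if (n_below_refs > 0) {
    extra <- sprintf("LOWREF%03d", seq_len(n_below_refs))
    low <- rel(disease_a, extra,
               sample(c("positive", "negative"), n_below_refs, TRUE),
               "disease", "gene", n_below_refs)
    low$ref_count <- sample(1:2, n_below_refs, replace = TRUE)
    rows <- c(rows, list(low))
  }
  if (n_unknown_polarity > 0) {
    extra <- sprintf("NOPOL%03d", seq_len(n_unknown_polarity))
    rows <- c(rows, list(rel(disease_a, extra, "unknown", "disease", "gene",
                             n_unknown_polarity)))
  }
  relations <- do.call(rbind, rows)
  relations <- relations[sample(nrow(relations)), , drop = FALSE]
  rownames(relations) <- NULL
  list(relations = as_relation_table(relations),
       truth = data.frame(gene = genes, group = group,
                          stringsAsFactors = FALSE))
}

#' The packaged eleven-gene protective network fixture
#'
#' The signed relation table behind the published protective
#' obesity-to-myocardial-infarction network: eleven genes (NPPB, NPPA, IRS1,
#' SMAD3, MIR155, ADRB1, AVP, MAPK14, MC3R, ROCK1, COL3A1), each inhibited
#' by obesity and promoting MI — 22 relations in total. Reference counts are
#' synthetic placeholders (all pass QC); the gene list and edge polarities
#' follow the published network.
#'
#' @return A `relation_table` with 22 rows.
#' @export
mi_promoter_fixture <- function() {
  read_relations(system.file("extdata", "obesity_mi_network.tsv",
                             package = "megasignet", mustWork = TRUE))
}

#' The packaged synthetic PTH shortest-path fixture
#'
#' A small signed network for path exploration between the parathyroid
#' hormone gene (PTH) and myocardial infarction. Only MMP9 and CTNNB1 are
#' literature-named intermediates; the remaining molecules are synthetic
#' placeholders (SYN-prefixed) standing in for unnamed nodes, so that PTH
#' reaches MI through both promoter-class and inhibitor-class intermediates.
#'
#' @return A `relation_table`.
#' @export
pth_path_fixture <- function() {
  read_relations(system.file("extdata", "pth_mi_paths_synthetic.tsv",
                             package = "megasignet", mustWork = TRUE))
}
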