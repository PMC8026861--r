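#' Pipeline run configuration
#'
#' Collects the thresholds and paths driving [run_pipeline()]. Thresholds
#' default to the values used throughout the analysis: relations need at
#' least 3 supporting references; pooled genes are called significant at
#' |LFC| > 1 and p < 0.05; enriched sets pass at q <= 0.005, set size
#' <= 1000 and overlap >= 2%.
#'
#' @param relations_file Path to a relation TSV (default: simulate).
#' @param gmt_file Path to a GMT collection (default: the packaged synthetic
#'   collection).
#' @param disease_a,disease_b Upstream / downstream disease identifiers.
#' @param min_refs,lfc_cut,p_cut,q_cut,set_size_max,overlap_min_percent
#'   Stage thresholds; see Details.
#' @param n_genes Number of genes simulated when no expression data is given.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(relations_file = NULL, gmt_file = NULL,
                       disease_a = "OBESITY", disease_b = "MI",
                       min_refs = 3, lfc_cut = 1.0, p_cut = 0.05,
                       q_cut = 0.005, set_size_max = 1000,
                       overlap_min_percent = 2, n_genes = 500, seed = 1,
                       out_dir = "megasignet_out") {
  thresholds <- c(min_refs = min_refs, lfc_cut = lfc_cut, p_cut = p_cut,
                  q_cut = q_cut, set_size_max = set_size_max,
                  overlap_min_percent = overlap_min_percent)
  if (any(thresholds <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  for (f in c(relations_file, gmt_file))
    if (!is.null(f) && !file.exists(f))
      stop("input path does not exist: ", f, call. = FALSE)
  structure(list(relations_file = relations_file, gmt_file = gmt_file,
                 disease_a = toupper(disease_a),
                 disease_b = toupper(disease_b),
                 min_refs = min_refs, lfc_cut = lfc_cut, p_cut = p_cut,
                 q_cut = q_cut, set_size_max = set_size_max,
                 overlap_min_percent = overlap_min_percent,
                 n_genes = n_genes, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

# Manifest written next to every pipeline run: config echo + hash, seed,
# package version. Makes any output directory self-describing.
.write_manifest <- function(config, out_dir) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  # hash the scientific configuration only; the output location is not part
  # of a run's identity
  hashed <- unclass(config)
  hashed$out_dir <- NULL
  hash_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(hash_file))
  yaml::write_yaml(hashed, hash_file)
  manifest <- list(
    package = "megasignet",
    version = as.character(utils::packageVersion("megasignet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(hash_file)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Wires the stages into one workflow: relation QC and protective-network
#' construction, per-gene expression mega-analysis on simulated multi-study
#' data, over-representation analysis of the protective genes, and signed
#' shortest-path exploration. Every stage writes plain TSV/JSON artifacts to
#' `config$out_dir` so it can be rerun or inspected in isolation, plus a
#' manifest (config hash, seed, versions).
#'
#' @param stage One of `"all"`, `"simulate"`, `"relations"`, `"mega"`,
#'   `"enrich"`, `"paths"`.
#' @param config A [run_config()].
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "relations", "mega",
                                   "enrich", "paths"),
                         config = run_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_manifest(config, config$out_dir)
  results <- list()
  want <- function(s) stage %in% c("all", s)

  relations <- if (!is.null(config$relations_file)) {
    read_relations(config$relations_file)
  } else {
    sim <- simulate_relations(config$disease_a, config$disease_b,
                              seed = config$seed)
    results$relations_truth <- sim$truth
    sim$relations
  }
  clean <- qc_filter(relations, min_refs = config$min_refs)
  message("relations: ", nrow(relations), " rows, ", nrow(clean),
          " pass QC (min_refs = ", config$min_refs, ")")

  if (want("simulate") && is.null(config$relations_file)) {
    utils::write.table(relations, file.path(config$out_dir, "relations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (want("relations")) {
    acct <- account_gene_sets(clean, config$disease_a, config$disease_b)
    nets <- protective_networks(clean, config$disease_a, config$disease_b)
    message("accounting: ", acct$counts[["targets_a"]], " targets / ",
            acct$counts[["regulators_b"]], " regulators / ",
            acct$counts[["shared"]], " shared / ",
            acct$counts[["a_only"]], " ", config$disease_a, "-only")
    message("protective networks: ",
            length(nets$genes$inhibited_promoters), " inhibited promoters, ",
            length(nets$genes$activated_inhibitors), " activated inhibitors")
    write_signed_network(nets$inhibited_promoters,
                         file.path(config$out_dir, "inhibited_promoters.tsv"))
    write_signed_network(nets$activated_inhibitors,
                         file.path(config$out_dir, "activated_inhibitors.tsv"))
    results$accounting <- acct
    results$networks <- nets
  }
  if (want("mega")) {
    sim <- simulate_expression(sim_config(n_genes = config$n_genes,
                                          seed = config$seed))
    mega <- mega_analysis(sim$datasets)
    sig <- significant_genes(mega, config$lfc_cut, config$p_cut)
    message("mega-analysis: ", sum(mega$analyzable), " genes pooled (",
            sum(mega$model == "fixed", na.rm = TRUE), " fixed / ",
            sum(mega$model == "random", na.rm = TRUE), " random), ",
            nrow(sig), " significant at |LFC| > ", config$lfc_cut,
            " and p < ", config$p_cut)
    write_mega_results(mega, file.path(config$out_dir, "mega_results.tsv"))
    write_mega_results(sig, file.path(config$out_dir, "mega_significant.tsv"))
    utils::write.table(volcano_data(mega),
                       file.path(config$out_dir, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_qq_report(qq_check(sim$datasets[[1]]),
                    file.path(config$out_dir, "qq_report.json"))
    results$mega <- mega
    results$significant <- sig
  }
  if (want("enrich")) {
    gmt <- if (!is.null(config$gmt_file)) config$gmt_file
           else system.file("extdata", "go_synthetic.gmt",
                            package = "megasignet", mustWork = TRUE)
    sets <- read_gmt(gmt)
    nets <- if (!is.null(results$networks)) results$networks
            else protective_networks(clean, config$disease_a, config$disease_b)
    query <- nets$genes$inhibited_promoters
    if (length(query) == 0) {
      message("enrichment skipped: no inhibited-promoter genes")
    } else {
      background <- unique(c(unlist(lapply(sets, `[[`, "members")), query))
      enr <- enrich(query, sets, background = background,
                    q_cut = config$q_cut,
                    set_size_max = config$set_size_max,
                    overlap_min_percent = config$overlap_min_percent)
      message("enrichment: ", sum(enr$passed), " of ", nrow(enr),
              " sets pass (q <= ", config$q_cut, ", size <= ",
              config$set_size_max, ", overlap >= ",
              config$overlap_min_percent, "%)")
      utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$enrichment <- enr
    }
  }
  if (want("paths")) {
    net <- signed_network(clean)
    src <- config$disease_a
    if (src %in% net$nodes$id && config$disease_b %in% net$nodes$id) {
      paths <- shortest_signed_paths(net, src, config$disease_b)
      roles <- if (nrow(paths) > 0)
        classify_intermediates(paths, clean, config$disease_b) else NULL
      message("paths: ", nrow(paths), " shortest path(s) from ", src, " to ",
              config$disease_b,
              if (!is.null(roles)) paste0("; verdict ", roles$verdict) else "")
      write_signed_paths(paths, file.path(config$out_dir, "paths.tsv"))
      results$paths <- paths
      results$path_roles <- roles
    } else {
      message("paths skipped: endpoints not both present in the network")
    }
  }
  invisible(results)
}
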