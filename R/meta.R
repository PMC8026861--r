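#' Construct a case-control expression dataset
#'
#' A lightweight container for one study: a genes-by-samples expression matrix
#' on the log2 scale together with per-sample group labels.
#'
#' @param dataset_id Study identifier.
#' @param matrix Numeric genes x samples matrix with unique rownames (gene
#'   symbols, upper-cased) and colnames (sample ids).
#' @param groups Character/factor of length `ncol(matrix)` with values
#'   `"case"` or `"control"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, groups) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) stop("matrix must have gene rownames")
  rownames(matrix) <- toupper(rownames(matrix))
  if (anyDuplicated(rownames(matrix)))
    stop("gene identifiers must be unique; collapse probes first")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix))
    stop("groups must have one label per sample column")
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  n_case <- sum(groups == "case")
  n_control <- sum(groups == "control")
  if (n_case < 1 || n_control < 1)
    stop("both groups need at least one sample")
  structure(list(dataset_id = as.character(dataset_id), matrix = matrix,
                 groups = groups, n_case = n_case, n_control = n_control),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset", x$dataset_id, ":", nrow(x$matrix), "genes,",
      x$n_case, "cases /", x$n_control, "controls\n")
  invisible(x)
}

#' Ensure an expression matrix is on the log2 scale
#'
#' Applies the heuristic used throughout the pipeline: a matrix whose maximum
#' exceeds `linear_max` is taken to be on the linear scale and transformed to
#' `log2(x + 1)`; otherwise it is returned unchanged. The branch taken is
#' recorded in the attribute `"log2_transformed"`.
#'
#' @param dataset An `expression_dataset`.
#' @param linear_max Threshold above which values are considered linear-scale;
#'   default 30.
#' @return The dataset, log2-transformed if needed.
#' @export
normalize_log2 <- function(dataset, linear_max = 30) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$matrix
  if (!all(is.finite(m))) stop("expression values must all be finite")
  transformed <- FALSE
  if (max(m) > linear_max) {
    if (any(m < 0))
      stop("negative values on the linear branch; cannot log2-transform")
    dataset$matrix <- log2(m + 1)
    transformed <- TRUE
  }
  attr(dataset, "log2_transformed") <- transformed
  dataset
}

#' Collapse probe-level rows to gene-level rows
#'
#' Maps probes to gene symbols and summarises each gene as the per-sample
#' median over its probes. Probes without a mapping are dropped.
#'
#' @param matrix Numeric probes x samples matrix with probe rownames.
#' @param probe_to_gene Data frame with columns `probe` and `gene`.
#' @return A genes x samples matrix with gene rownames, sorted by gene.
#' @export
collapse_probes <- function(matrix, probe_to_gene) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  stopifnot(all(c("probe", "gene") %in% names(probe_to_gene)))
  map <- probe_to_gene[probe_to_gene$probe %in% rownames(matrix), , drop = FALSE]
  if (nrow(map) == 0) {
    warning("no probes map to genes; returning an empty matrix", call. = FALSE)
    out <- matrix[0, , drop = FALSE]
    return(out)
  }
  genes <- sort(unique(toupper(map$gene)))
  out <- base::matrix(NA_real_, nrow = length(genes), ncol = ncol(matrix),
                      dimnames = list(genes, colnames(matrix)))
  for (g in genes) {
    probes <- map$probe[toupper(map$gene) == g]
    sub <- matrix[rownames(matrix) %in% probes, , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median)
  }
  out
}

# Row means and unbiased row variances, computed with explicit centering.
.row_mean_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n < 2) return(list(mean = mu, var = rep(NA_real_, nrow(m)), n = n))
  v <- rowSums((m - mu)^2) / (n - 1)
  list(mean = mu, var = v, n = n)
}

#' Per-gene effect sizes for one dataset
#'
#' For every gene, computes the log2 fold-change `lfc = mean(case) -
#' mean(control)` and its unpooled (Welch-style) sampling variance
#' `s2_case/n_case + s2_control/n_control`.
#'
#' @param dataset An `expression_dataset` with at least 2 samples per group.
#' @param genes Optional character vector restricting the genes (absent genes
#'   are silently omitted).
#' @return A data frame with columns `dataset_id`, `gene`, `lfc`, `var`,
#'   `n_case`, `n_control`.
#' @export
dataset_effects <- function(dataset, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$n_case < 2 || dataset$n_control < 2)
    stop("dataset ", dataset$dataset_id,
         ": both groups need >= 2 samples for a variance")
  m <- dataset$matrix
  if (!is.null(genes)) {
    genes <- toupper(genes)
    m <- m[rownames(m) %in% genes, , drop = FALSE]
  }
  cs <- .row_mean_var(m[, dataset$groups == "case", drop = FALSE])
  ct <- .row_mean_var(m[, dataset$groups == "control", drop = FALSE])
  data.frame(
    dataset_id = rep(dataset$dataset_id, nrow(m)),
    gene = rownames(m),
    lfc = unname(cs$mean - ct$mean),
    var = unname(cs$var / cs$n + ct$var / ct$n),
    n_case = rep(cs$n, nrow(m)),
    n_control = rep(ct$n, nrow(m)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Effect size of a single gene in one dataset
#'
#' @inheritParams dataset_effects
#' @param gene Gene symbol.
#' @return A one-row data frame as in [dataset_effects()], or `NULL` when the
#'   gene is absent from the dataset.
#' @export
dataset_effect <- function(dataset, gene) {
  eff <- dataset_effects(dataset, genes = gene)
  if (nrow(eff) == 0) return(NULL)
  eff
}

#' Cochran's Q heterogeneity statistic
#'
#' With fixed-effect weights `w_i = 1/var_i` and the inverse-variance pooled
#' mean `theta_hat`, `Q = sum(w_i * (lfc_i - theta_hat)^2)` with `df = k - 1`.
#'
#' @param lfc Numeric vector of per-dataset effect sizes.
#' @param var Numeric vector of their sampling variances (all > 0).
#' @return A list with elements `Q` and `df`.
#' @export
cochran_q <- function(lfc, var) {
  k <- length(lfc)
  if (k == 0) stop("at least one effect is required")
  stopifnot(length(var) == k, all(var > 0))
  w <- 1 / var
  theta <- sum(w * lfc) / sum(w)
  list(Q = sum(w * (lfc - theta)^2), df = k - 1L)
}

#' I-squared heterogeneity percentage
#'
#' The percentage of total variation attributable to between-study
#' heterogeneity: 0 whenever `Q <= df` (the observed dispersion does not
#' exceed its expectation under homogeneity), otherwise
#' `100 * (Q - df) / Q`.
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param df Degrees of freedom, `k - 1`.
#' @return A percentage in `[0, 100)`.
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 0)
  if (Q <= df) return(0)
  100 * (Q - df) / Q
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator `tau2 = max(0, (Q - df) / (S1 - S2/S1))` with
#' `S1 = sum(w_i)`, `S2 = sum(w_i^2)` and fixed-effect weights `w_i = 1/var_i`.
#'
#' @inheritParams cochran_q
#' @return The non-negative estimate of the between-study variance.
#' @export
dl_tau2 <- function(lfc, var) {
  k <- length(lfc)
  if (k < 2) stop("at least two effects are required to estimate tau2")
  stopifnot(length(var) == k, all(var > 0))
  w <- 1 / var
  q <- cochran_q(lfc, var)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q$Q - q$df) / denom)
}

#' Pool per-dataset effects for one gene
#'
#' Implements the heterogeneity-driven model choice: Cochran's Q is compared
#' with its degrees of freedom; when `Q <= df` the I-squared is set to zero
#' and the fixed-effect model (weights `1/var_i`) is used, otherwise the
#' DerSimonian-Laird random-effects model (weights `1/(var_i + tau2)`).
#' The pooled effect is the weighted mean, its standard error
#' `1/sqrt(sum(w))`, and the p-value a two-sided Wald z-test.
#'
#' @param effects A data frame with columns `lfc` and `var` (one row per
#'   dataset), as produced by [dataset_effects()]; may carry `gene`.
#' @return A one-row data frame of class `meta_result` with columns `gene`,
#'   `k`, `pooled_lfc`, `se`, `p`, `Q`, `df`, `isq`, `tau2`, `model`.
#' @export
pool_effects <- function(effects) {
  stopifnot(is.data.frame(effects), all(c("lfc", "var") %in% names(effects)))
  k <- nrow(effects)
  if (k < 2) stop("pooling requires at least two datasets (k >= 2)")
  bad <- which(!(effects$var > 0))
  if (length(bad) > 0) {
    id <- if ("dataset_id" %in% names(effects))
      paste(effects$dataset_id[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    stop("non-positive sampling variance in dataset(s): ", id)
  }
  fit <- .pool_core(effects$lfc, effects$var)
  gene <- if ("gene" %in% names(effects)) effects$gene[1] else NA_character_
  out <- data.frame(gene = gene, k = k, pooled_lfc = fit$est, se = fit$se,
                    p = fit$p, Q = fit$Q, df = fit$df, isq = fit$isq,
                    tau2 = fit$tau2, model = fit$model,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

# Pooling core shared by pool_effects() and mega_analysis().
.pool_core <- function(lfc, var) {
  q <- cochran_q(lfc, var)
  isq <- i_squared(q$Q, q$df)
  if (q$Q <= q$df) {
    model <- "fixed"
    tau2 <- 0
    w <- 1 / var
  } else {
    model <- "random"
    tau2 <- dl_tau2(lfc, var)
    w <- 1 / (var + tau2)
  }
  est <- sum(w * lfc) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  list(est = est, se = se, p = p, Q = q$Q, df = q$df, isq = isq,
       tau2 = tau2, model = model)
}

#' Per-gene cross-dataset mega-analysis
#'
#' For every gene, gathers its effect size (log2 fold-change and Welch
#' variance) from each dataset that measures it and pools them with the
#' fixed/random model selection of [pool_effects()]. Genes measured in fewer
#' than two datasets are reported with `analyzable = FALSE` and carry no
#' pooled estimate. Benjamini-Hochberg q-values are reported alongside the
#' raw p-values but do not enter the significance call (see
#' [significant_genes()]).
#'
#' @param datasets A list of `expression_dataset` objects (>= 2).
#' @param genes Optional character vector of genes to analyse; default: the
#'   union of all genes across datasets.
#' @return A data frame of class `mega_result` sorted by p ascending (one row
#'   per gene) with columns `gene`, `k`, `analyzable`, `pooled_lfc`, `se`,
#'   `p`, `q_bh`, `Q`, `df`, `isq`, `tau2`, `model`.
#' @export
mega_analysis <- function(datasets, genes = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  for (d in datasets) stopifnot(inherits(d, "expression_dataset"))
  if (is.null(genes))
    genes <- unique(unlist(lapply(datasets, function(d) rownames(d$matrix))))
  genes <- toupper(genes)
  if (length(genes) == 0) {
    return(structure(data.frame(gene = character(), k = integer(),
                                analyzable = logical(), pooled_lfc = numeric(),
                                se = numeric(), p = numeric(), q_bh = numeric(),
                                Q = numeric(), df = integer(), isq = numeric(),
                                tau2 = numeric(), model = character(),
                                stringsAsFactors = FALSE),
                     class = c("mega_result", "data.frame")))
  }
  eff <- lapply(datasets, dataset_effects, genes = genes)
  nd <- length(datasets)
  lfc_m <- base::matrix(NA_real_, length(genes), nd,
                        dimnames = list(genes, NULL))
  var_m <- lfc_m
  for (j in seq_len(nd)) {
    e <- eff[[j]]
    lfc_m[e$gene, j] <- e$lfc
    var_m[e$gene, j] <- e$var
  }
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    ok <- which(is.finite(lfc_m[i, ]) & is.finite(var_m[i, ]) & var_m[i, ] > 0)
    k <- length(ok)
    if (k < 2) {
      rows[[i]] <- data.frame(gene = genes[i], k = k, analyzable = FALSE,
                              pooled_lfc = NA_real_, se = NA_real_,
                              p = NA_real_, Q = NA_real_, df = NA_integer_,
                              isq = NA_real_, tau2 = NA_real_,
                              model = NA_character_, stringsAsFactors = FALSE)
    } else {
      fit <- .pool_core(lfc_m[i, ok], var_m[i, ok])
      rows[[i]] <- data.frame(gene = genes[i], k = k, analyzable = TRUE,
                              pooled_lfc = fit$est, se = fit$se, p = fit$p,
                              Q = fit$Q, df = fit$df, isq = fit$isq,
                              tau2 = fit$tau2, model = fit$model,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- NA_real_
  out$q_bh[out$analyzable] <- bh_fdr(out$p[out$analyzable])
  out <- out[order(out$p, out$gene, na.last = TRUE), , drop = FALSE]
  out <- out[, c("gene", "k", "analyzable", "pooled_lfc", "se", "p", "q_bh",
                 "Q", "df", "isq", "tau2", "model")]
  rownames(out) <- NULL
  class(out) <- c("mega_result", "data.frame")
  out
}

#' Significant genes from a mega-analysis
#'
#' Applies the reporting rule for the pooled results: `pooled_lfc > lfc_cut`
#' or `pooled_lfc < -lfc_cut`, and `p < p_cut` — all inequalities strict.
#' Non-analyzable genes never qualify. No multiple-testing correction enters
#' this call; q-values are reported for reference only.
#'
#' @param results A `mega_result` data frame from [mega_analysis()].
#' @param lfc_cut Absolute log2 fold-change threshold; default 1.
#' @param p_cut P-value threshold; default 0.05.
#' @return The qualifying rows of `results`.
#' @export
significant_genes <- function(results, lfc_cut = 1.0, p_cut = 0.05) {
  stopifnot(is.data.frame(results))
  keep <- !is.na(results$p) & results$analyzable &
    (results$pooled_lfc > lfc_cut | results$pooled_lfc < -lfc_cut) &
    results$p < p_cut
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forest-plot table for one gene
#'
#' One row per dataset with its effect, 95% confidence interval
#' (`lfc +/- 1.96 * sqrt(var)`) and the percentage weight it received under
#' the selected pooling model, followed by a summary row with the pooled
#' estimate. Weights sum to 100.
#'
#' @param effects Per-dataset effects for the gene ([dataset_effects()] rows).
#' @param pooled The gene's one-row pooled result ([pool_effects()]).
#' @return A data frame with columns `dataset_id`, `lfc`, `ci_lo`, `ci_hi`,
#'   `weight_pct`, `row_type`.
#' @export
forest_data <- function(effects, pooled) {
  stopifnot(is.data.frame(effects), all(c("lfc", "var") %in% names(effects)))
  stopifnot(nrow(pooled) == 1)
  w <- if (pooled$model == "random") 1 / (effects$var + pooled$tau2)
       else 1 / effects$var
  wpct <- 100 * w / sum(w)
  half <- 1.96 * sqrt(effects$var)
  ids <- if ("dataset_id" %in% names(effects)) effects$dataset_id
         else paste0("study_", seq_len(nrow(effects)))
  rbind(
    data.frame(dataset_id = ids, lfc = effects$lfc,
               ci_lo = effects$lfc - half, ci_hi = effects$lfc + half,
               weight_pct = wpct, row_type = "study",
               stringsAsFactors = FALSE),
    data.frame(dataset_id = "pooled", lfc = pooled$pooled_lfc,
               ci_lo = pooled$pooled_lfc - 1.96 * pooled$se,
               ci_hi = pooled$pooled_lfc + 1.96 * pooled$se,
               weight_pct = 100, row_type = "summary",
               stringsAsFactors = FALSE)
  )
}

#' Volcano table for a mega-analysis
#'
#' @param results A `mega_result` data frame.
#' @return A data frame with `gene`, `pooled_lfc` and `neg_log10_p` for the
#'   analyzable genes.
#' @export
volcano_data <- function(results) {
  r <- results[results$analyzable, , drop = FALSE]
  data.frame(gene = r$gene, pooled_lfc = r$pooled_lfc,
             neg_log10_p = -log10(r$p), stringsAsFactors = FALSE)
}

# Kolmogorov-Smirnov sup-distance of a sample to the standard normal.
.ks_normal <- function(z) {
  z <- sort(z)
  n <- length(z)
  cdf <- stats::pnorm(z)
  max(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf))
}

#' QQ bias check for one dataset
#'
#' Computes per-gene standardized two-sample statistics `lfc / sqrt(var)`,
#' re-standardizes them by their own mean and standard deviation, and
#' compares the result with the standard normal via the Kolmogorov-Smirnov
#' sup-distance. A dataset whose genes deviate strongly from normality (KS
#' distance above `bias_threshold`) is flagged for systematic bias.
#'
#' @param dataset An `expression_dataset` with >= 2 samples per group.
#' @param bias_threshold KS distance above which the `systematic_bias` flag is
#'   set; default 0.1.
#' @return An object of class `qq_report`: a list with `dataset_id`,
#'   `statistic` (standardized, sorted), `theoretical` (standard-normal
#'   quantiles of matching plotting positions), `deviation` (KS distance) and
#'   `systematic_bias`.
#' @export
qq_check <- function(dataset, bias_threshold = 0.1) {
  eff <- dataset_effects(dataset)
  z <- eff$lfc / sqrt(eff$var)
  z <- z[is.finite(z)]
  if (length(z) < 2 || stats::sd(z) == 0)
    stop("degenerate input: no spread in the per-gene statistics")
  z <- (z - mean(z)) / stats::sd(z)
  z <- sort(z)
  n <- length(z)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  dev <- .ks_normal(z)
  structure(list(dataset_id = dataset$dataset_id, statistic = z,
                 theoretical = theo, deviation = dev,
                 systematic_bias = dev > bias_threshold),
            class = "qq_report")
}

#' @export
print.qq_report <- function(x, ...) {
  cat("QQ report for", x$dataset_id, ":", length(x$statistic), "genes, KS =",
      format(x$deviation, digits = 4),
      if (x$systematic_bias) "(systematic bias)" else "(no systematic bias)",
      "\n")
  invisible(x)
}
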