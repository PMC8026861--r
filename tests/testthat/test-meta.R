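test_that("log2 normalization transforms only linear-scale matrices", {
  d_log <- tiny_dataset(seed = 1)            # values around 8, max << 30
  out <- normalize_log2(d_log)
  expect_false(attr(out, "log2_transformed"))
  expect_identical(out$matrix, d_log$matrix)

  d_lin <- d_log
  d_lin$matrix <- matrix(c(1023, 0, 3, 7, 15, 1, 2, 4, 8, 16),
                         2, 5, dimnames = list(c("A", "B"), paste0("s", 1:5)))
  d_lin$groups <- c("case", "case", "case", "control", "control")
  out2 <- normalize_log2(d_lin)
  expect_true(attr(out2, "log2_transformed"))
  expect_equal(unname(out2$matrix["A", 1]), 10)  # log2(1024)
  expect_equal(unname(out2$matrix["B", 1]), 0)   # log2(0 + 1)

  d_neg <- d_lin
  d_neg$matrix[1, 1] <- -5
  d_neg$matrix[2, 1] <- 100
  expect_error(normalize_log2(d_neg), "negative")
})

test_that("probe collapsing takes per-sample medians and matches a group-by oracle", {
  m <- matrix(c(1, 2, 9,
                4, 5, 6), nrow = 3, ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = "GX")
  expect_equal(unname(collapse_probes(m, map)["GX", "s1"]), 2)

  set.seed(11)
  m2 <- matrix(rnorm(40), 10, 4,
               dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  map2 <- data.frame(probe = paste0("p", 1:10),
                     gene = sample(c("A", "B", "C"), 10, replace = TRUE))
  got <- collapse_probes(m2, map2)
  for (g in rownames(got)) for (s in colnames(got)) {
    expect_equal(got[g, s],
                 median(m2[map2$probe[map2$gene == g], s]))
  }
  # one probe per gene is the identity up to ordering
  map1 <- data.frame(probe = paste0("p", 1:10), gene = paste0("g", 10:1))
  one <- collapse_probes(m2, map1)
  expect_equal(one[toupper("g3"), ], m2["p8", ])
  expect_warning(collapse_probes(m2, data.frame(probe = "zz", gene = "A")),
                 "no probes map")
})

test_that("per-dataset effects use group-mean differences and Welch variances", {
  m <- matrix(c(4, 6, 1, 3), 1, 4,
              dimnames = list("G1", paste0("s", 1:4)))
  d <- expression_dataset("D", m, c("case", "case", "control", "control"))
  eff <- dataset_effect(d, "G1")
  expect_equal(eff$lfc, 3)       # mean(4,6) - mean(1,3)
  expect_equal(eff$var, 2)       # s2=2 each group: 2/2 + 2/2

  d0 <- tiny_dataset(seed = 2)
  eff0 <- dataset_effects(d0)
  shifted <- d0
  shifted$matrix[, d0$groups == "case"] <-
    shifted$matrix[, d0$groups == "case"] + 0.7
  effs <- dataset_effects(shifted)
  expect_equal(effs$lfc, eff0$lfc + 0.7)       # translation equivariance
  expect_equal(effs$var, eff0$var)

  same <- expression_dataset("S", matrix(rep(c(5, 7), 4), 1, 8,
                             dimnames = list("G1", paste0("s", 1:8))),
                             rep(c("case", "control"), each = 4))
  expect_equal(dataset_effect(same, "G1")$lfc, 0)
  expect_null(dataset_effect(d0, "NOT_A_GENE"))
  tiny <- expression_dataset("X", matrix(1:4, 1, 4,
                             dimnames = list("G1", paste0("s", 1:4))),
                             c("case", rep("control", 3)))
  expect_error(dataset_effects(tiny), ">= 2 samples")
})

test_that("Q, I-squared and DL tau2 follow their defining formulas", {
  expect_equal(cochran_q(1.5, 0.2)$Q, 0)
  expect_equal(cochran_q(1.5, 0.2)$df, 0)
  expect_equal(cochran_q(c(2, 2, 2), c(1, 2, 3))$Q, 0)
  expect_error(cochran_q(numeric(0), numeric(0)), "at least one")

  expect_equal(i_squared(3, 4), 0)
  expect_equal(i_squared(4, 4), 0)
  expect_equal(i_squared(10, 4), 60)

  expect_equal(dl_tau2(c(1, 1.1, 0.9), c(1, 1, 1)), 0)  # Q < df -> truncated
  expect_error(dl_tau2(1, 1), "at least two")

  yi <- c(0.4, -1.2, 2.5)
  vi <- c(0.3, 0.8, 1.7)
  want <- oracle_meta(yi, vi)
  q <- cochran_q(yi, vi)
  expect_equal(q$Q, want$Q, tolerance = 1e-12)
  expect_equal(dl_tau2(yi, vi), want$tau2, tolerance = 1e-12)
})

test_that("pooling matches the independent oracle and selects models consistently", {
  set.seed(101)
  for (rep in 1:300) {
    k <- sample(2:8, 1)
    yi <- rnorm(k, sd = 2)
    vi <- runif(k, 0.05, 2)
    got <- pool_effects(data.frame(gene = "G", lfc = yi, var = vi))
    want <- oracle_meta(yi, vi)
    expect_equal(got$Q, want$Q, tolerance = 1e-10)
    expect_equal(got$tau2, want$tau2_used, tolerance = 1e-10)
    expect_equal(got$pooled_lfc, want$est, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$model, want$model)
    # model selection triple equivalence
    expect_identical(got$model == "fixed", got$Q <= got$df)
    expect_identical(got$isq == 0, got$Q <= got$df)
  }
})

test_that("pooling agrees with metafor's DL fit on heterogeneous instances", {
  skip_if_not_installed("metafor")
  set.seed(55)
  checked <- 0
  while (checked < 25) {
    k <- sample(3:8, 1)
    yi <- rnorm(k, sd = 3)
    vi <- runif(k, 0.05, 1)
    got <- pool_effects(data.frame(lfc = yi, var = vi))
    if (got$model != "random") next   # metafor DL has no Q<=df fixed switch
    fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
    expect_equal(got$tau2, fit$tau2, tolerance = 1e-8)
    expect_equal(got$pooled_lfc, unname(fit$beta[1]), tolerance = 1e-8)
    expect_equal(got$se, fit$se, tolerance = 1e-8)
    expect_equal(got$Q, fit$QE, tolerance = 1e-8)
    checked <- checked + 1
  }
})

test_that("equal-variance fixed pooling is the mean; tau2 = 0 collapses the models", {
  got <- pool_effects(data.frame(lfc = c(1, 2), var = c(0.5, 0.5)))
  expect_equal(got$pooled_lfc, 1.5)
  expect_equal(got$model, "fixed")

  yi <- c(0.2, 0.25, 0.22, 0.21)
  vi <- c(0.4, 0.5, 0.45, 0.42)
  got2 <- pool_effects(data.frame(lfc = yi, var = vi))
  expect_equal(got2$tau2, 0)
  w <- 1 / vi
  expect_equal(got2$pooled_lfc, sum(w * yi) / sum(w))  # fixed = random at tau2 0

  expect_error(pool_effects(data.frame(lfc = 1, var = 1)), "at least two")
  expect_error(pool_effects(data.frame(dataset_id = c("A", "B"),
                                       lfc = c(1, 2), var = c(1, 0))), "B")
})

test_that("mega-analysis handles missing genes and shifts under translation", {
  d1 <- tiny_dataset("D1", n_genes = 8, seed = 1)
  d2 <- tiny_dataset("D2", n_genes = 8, seed = 2)
  d3 <- tiny_dataset("D3", n_genes = 8, seed = 3)
  # restrict D2/D3 to the first 6 genes; G007/G008 then appear in one dataset
  d2$matrix <- d2$matrix[1:6, , drop = FALSE]
  d3$matrix <- d3$matrix[1:6, , drop = FALSE]
  res <- mega_analysis(list(d1, d2, d3))
  expect_equal(sum(!res$analyzable), 2)
  expect_true(all(res$k[!res$analyzable] == 1))
  expect_true(all(is.na(res$pooled_lfc[!res$analyzable])))
  expect_equal(nrow(significant_genes(res, 0, 2)), sum(res$analyzable))
  expect_true(!is.unsorted(res$p[res$analyzable]))

  shift <- 0.9
  sh <- lapply(list(d1, d2, d3), function(d) {
    d$matrix[, d$groups == "case"] <- d$matrix[, d$groups == "case"] + shift
    d
  })
  res_sh <- mega_analysis(sh)
  merged <- merge(res[res$analyzable, c("gene", "pooled_lfc")],
                  res_sh[res_sh$analyzable, c("gene", "pooled_lfc")],
                  by = "gene")
  expect_equal(merged$pooled_lfc.y, merged$pooled_lfc.x + shift,
               tolerance = 1e-12)
  expect_equal(nrow(mega_analysis(list(d1, d2), genes = character(0))), 0)
})

test_that("the significance rule uses strict cuts on both LFC and p", {
  res <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    k = 3, analyzable = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    pooled_lfc = c(-11.52, 0.5, 1.0, 1.4, 5),
    se = 1, p = c(0.016, 0.001, 0.01, 0.05, 0.001),
    q_bh = NA, Q = 1, df = 2, isq = 0, tau2 = 0, model = "fixed")
  sig <- significant_genes(res)
  expect_equal(sig$gene, "A")  # B fails |LFC|, C fails strict >1, D strict p, E not analyzable
  sig2 <- significant_genes(transform(res, p = c(0.016, 0.001, 0.01, 0.049, 0.001)))
  expect_setequal(sig2$gene, c("A", "D"))
})

test_that("forest tables carry 1.96-sigma intervals and weights summing to 100", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    eff <- data.frame(dataset_id = paste0("D", 1:k),
                      lfc = rnorm(k), var = runif(k, 0.05, 1))
    pooled <- pool_effects(eff)
    ft <- forest_data(eff, pooled)
    study <- ft[ft$row_type == "study", ]
    expect_equal(sum(study$weight_pct), 100, tolerance = 1e-9)
    expect_equal(study$ci_hi - study$lfc, 1.96 * sqrt(eff$var))
    expect_equal(which.max(study$weight_pct),
                 which.max(1 / (eff$var + pooled$tau2)))
    expect_equal(ft$lfc[ft$row_type == "summary"], pooled$pooled_lfc)
  }
})

test_that("QQ check is calm under the null and rejects degenerate input", {
  cfg <- sim_config(dataset_designs = data.frame(dataset_id = "Q1",
                                                 n_control = 40, n_case = 40),
                    n_genes = 5000, planted_lfc = 0, tau2 = 0, seed = 9)
  d <- simulate_expression(cfg)$datasets[[1]]
  rep <- qq_check(d)
  expect_lt(rep$deviation, 0.03)
  expect_false(rep$systematic_bias)
  expect_equal(length(rep$statistic), length(rep$theoretical))

  # one extreme outlier gene among 5000 cannot trip the KS flag
  d_out <- d
  d_out$matrix[1, d_out$groups == "case"] <-
    d_out$matrix[1, d_out$groups == "case"] + 8
  out_rep <- qq_check(d_out)
  expect_gt(max(abs(out_rep$statistic)), 10)  # the outlier is genuinely extreme
  expect_false(out_rep$systematic_bias)

  const <- expression_dataset("C", matrix(5, 3, 6,
                              dimnames = list(paste0("g", 1:3), paste0("s", 1:6))),
                              rep(c("case", "control"), each = 3))
  expect_error(qq_check(const), "degenerate")
})
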