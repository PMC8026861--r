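test_that("reading preserves rows and stages unknown polarity for QC", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject\tsubject_kind\tobject\tobject_kind\tpolarity\trelation_class\tref_count",
    "Obesity\tdisease\tnppb\tgene\tnegative\tregulation\t4",
    "obesity\tdisease\tFoo\tgene\tWeird\tregulation\t10",
    "BAR\tgene\tMI\tdisease\tpositive\tregulation\t2"
  ), tmp)
  rel <- read_relations(tmp)
  expect_equal(nrow(rel), 3)
  expect_equal(rel$subject[1], "OBESITY")
  expect_equal(rel$object[1], "NPPB")
  expect_equal(rel$polarity[2], "unknown")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tobject\tpolarity", "A\tB\tpositive"), bad)
  expect_error(read_relations(bad), "ref_count")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("subject\tobject\tpolarity\tref_count", empty)
  expect_warning(out <- read_relations(empty), "no data rows")
  expect_equal(nrow(out), 0)
})

test_that("the packaged eleven-gene network fixture has 22 relations", {
  rel <- mi_promoter_fixture()
  expect_equal(nrow(rel), 22)
  expect_equal(sum(rel$subject == "OBESITY"), 11)
  expect_equal(sum(rel$object == "MI"), 11)
})

test_that("QC removes sub-threshold evidence and unclear polarity, idempotently", {
  df <- data.frame(
    subject = c("OBESITY", "OBESITY", "OBESITY", "G1"),
    object = c("G1", "G2", "G3", "MI"),
    polarity = c("negative", "positive", "unknown", "positive"),
    ref_count = c(2, 3, 10, 7)
  )
  rel <- as_relation_table(df)
  clean <- qc_filter(rel, min_refs = 3)
  expect_equal(clean$object, c("G2", "MI"))  # refs<3 and unknown both removed
  expect_identical(qc_filter(clean, 3), clean)
  expect_equal(nrow(qc_filter(rel[0, ], 3)), 0)
})

test_that("conflicting polarities aggregate by summed evidence, ties undefined", {
  df <- data.frame(
    subject = rep("OBESITY", 5),
    object = c("G1", "G1", "G1", "G2", "G2"),
    polarity = c("positive", "negative", "negative", "positive", "negative"),
    ref_count = c(5, 3, 3, 4, 4)
  )
  net <- signed_network(as_relation_table(df))
  # G1: negative wins 6 > 5; G2: exact tie -> undefined, dropped
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$object, "G1")
  expect_equal(net$edges$polarity, -1L)
  expect_equal(net$edges$ref_count, 11L)
})

test_that("set accounting matches brute-force set algebra on random fixtures", {
  for (seed in 1:5) {
    rel <- as_relation_table(random_relation_df(n_genes = 30, seed = seed))
    acct <- account_gene_sets(rel, "obesity", "mi")
    targets <- unique(rel$object[rel$subject == "OBESITY"])
    regs <- unique(rel$subject[rel$object == "MI"])
    expect_setequal(acct$targets_a$gene, targets)
    expect_setequal(acct$regulators_b$gene, regs)
    expect_setequal(acct$shared, intersect(targets, regs))
    expect_setequal(acct$a_only, setdiff(targets, regs))
    expect_equal(acct$counts[["a_only"]] + acct$counts[["shared"]],
                 acct$counts[["targets_a"]])
  }
  expect_warning(
    empty <- account_gene_sets(as_relation_table(random_relation_df(5, 1)),
                               "NOSUCH", "MI"),
    "not found")
  expect_equal(unname(empty$counts[c("targets_a", "shared")]), c(0L, 0L))

  disjoint <- as_relation_table(data.frame(
    subject = c("OBESITY", "G9"), object = c("G1", "MI"),
    polarity = "positive", ref_count = 5))
  expect_equal(account_gene_sets(disjoint, "OBESITY", "MI")$counts[["shared"]], 0L)
})

test_that("protective networks match the exhaustive sign-pair oracle", {
  for (seed in 1:8) {
    rel <- as_relation_table(random_relation_df(n_genes = 25, seed = seed))
    nets <- protective_networks(rel, "OBESITY", "MI")
    want <- oracle_protective(rel, "OBESITY", "MI")
    expect_equal(nets$genes$inhibited_promoters, want$inhibited_promoters)
    expect_equal(nets$genes$activated_inhibitors, want$activated_inhibitors)
  }
})

test_that("protective membership ignores row order and duplicated rows", {
  rel <- as_relation_table(random_relation_df(n_genes = 20, seed = 42))
  base_genes <- protective_networks(rel, "OBESITY", "MI")$genes
  shuffled <- rel[sample(nrow(rel)), ]
  doubled <- rbind(rel, rel)
  expect_equal(protective_networks(shuffled, "OBESITY", "MI")$genes, base_genes)
  expect_equal(protective_networks(doubled, "OBESITY", "MI")$genes, base_genes)
})

test_that("a concordant-positive gene joins neither protective network", {
  df <- data.frame(subject = c("OBESITY", "G1"), object = c("G1", "MI"),
                   polarity = "positive", ref_count = 5)
  nets <- protective_networks(as_relation_table(df), "OBESITY", "MI")
  expect_length(nets$genes$inhibited_promoters, 0)
  expect_length(nets$genes$activated_inhibitors, 0)
})

test_that("network round-trips through TSV, DOT and igraph with polarity intact", {
  net <- signed_network(qc_filter(mi_promoter_fixture()))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_signed_network(net, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 22)
  expect_setequal(unique(back$polarity), c(1L, -1L))

  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), 13)  # 11 genes + 2 diseases
  expect_setequal(unique(igraph::E(g)$polarity), c(1, -1))

  dot <- withr::local_tempfile(fileext = ".dot")
  write_network_dot(net, dot)
  lines <- readLines(dot)
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), 22)
})
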