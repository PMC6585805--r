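test_that("peptides collapse to parent gene symbols", {
  ann <- read_peptide_annotations()
  expect_equal(map_peptides_to_genes(c("PAXI_111_123", "PAXI_24_36"), ann),
               "PXN")
  expect_equal(map_peptides_to_genes("ART_004_EAIYAAPFAKKKXC", ann), "ABL1")
  expect_equal(map_peptides_to_genes(character(), ann), character())
  # the internal positive control never contributes a gene
  expect_equal(map_peptides_to_genes(
    c("ART_003_EAIYAAPFAKKKXC", "CDK2_8_20"), ann), "CDK2")
  err <- tryCatch(map_peptides_to_genes("NOT_A_PEPTIDE", ann),
                  error = identity)
  expect_s3_class(err, "kk_validation_error")
  expect_match(conditionMessage(err), "NOT_A_PEPTIDE")
  # collapsing is idempotent: a collapsed list maps onto itself
  pub <- load_published_calls()
  genes <- map_peptides_to_genes(pub$peptide_id, ann)
  expect_equal(sort(unique(toupper(genes)), method = "radix"), genes)
})

test_that("hypergeometric enrichment matches combinatorial summation", {
  # hand-enumerable case: N = 10, K = 5, n = 4, k = 3
  r <- hypergeom_enrichment(c("A", "B", "C", "X"), c("A", "B", "C", "D", "E"),
                            background_size = 10)
  expect_equal(r$k, 3L)
  expect_equal(r$p_value, 55 / 210, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_hyper_p(3, 5, 4, 10), tolerance = 1e-12)
  # hits identical to the set
  hits <- c("G1", "G2", "G3", "G4")
  r2 <- hypergeom_enrichment(hits, hits, background_size = 100)
  expect_equal(r2$p_value, 1 / choose(100, 4), tolerance = 1e-12)
  expect_equal(r2$p_value, oracle_hyper_p(4, 4, 4, 100), tolerance = 1e-12)
  # right tail includes k = 0, so no overlap means p = 1
  r3 <- hypergeom_enrichment(c("A", "B"), c("C", "D"), background_size = 20000)
  expect_equal(r3$p_value, 1)
  # p is non-increasing in k at fixed N, K, n
  set <- sprintf("S%d", 1:10)
  ps <- vapply(0:4, function(k) {
    hits <- c(set[seq_len(k)], sprintf("X%d", seq_len(4 - k)))
    hypergeom_enrichment(hits, set, background_size = 1000)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeom_enrichment(letters, LETTERS, background_size = 10),
               class = "kk_validation_error")
})

test_that("the enrichment table composes per-set tests with membership flags", {
  sets <- read_gene_sets(system.file("extdata", "gene_sets_synthetic.gmt",
                                     package = "kinomekin"))
  hits_a <- c("PTK2", "PXN", "PIK3R1", "MAPK1")
  hits_b <- c("PXN", "PIK3R1", "LCK")
  et <- enrichment_table(list(ECM = hits_a, Ti = hits_b), sets,
                         background_size = 20000)
  # each row equals a direct per-set call
  for (i in seq_len(nrow(et$results))) {
    row <- et$results[i, ]
    hits <- if (row$condition == "ECM") hits_a else hits_b
    expect_equal(row$p_value,
                 hypergeom_enrichment(hits, sets[[row$set_name]],
                                      background_size = 20000)$p_value)
  }
  # identical hit lists give identical p-values
  et2 <- enrichment_table(list(A = hits_a, B = hits_a), sets)
  pa <- et2$results$p_value[et2$results$condition == "A"]
  pb <- et2$results$p_value[et2$results$condition == "B"]
  expect_equal(pa, pb)
  # membership flags
  m <- et$membership
  expect_equal(m["PXN", "FOCAL_ADHESION"], "both")
  expect_equal(m["PTK2", "FOCAL_ADHESION"], "a_only")
  expect_equal(m["LCK", "IMMUNE_RECEPTOR"], "b_only")
  expect_equal(m["LCK", "FOCAL_ADHESION"], "none")
  expect_error(enrichment_table(list(A = hits_a), list()),
               class = "kk_validation_error")
})
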