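test_that("per-cell metrics follow the stated arithmetic and conventions", {
  dense <- matrix(0, 3, 2, dimnames = NULL)
  dense[1, 1] <- 5   # geneA
  dense[3, 1] <- 5   # MT-CO1
  cm <- count_matrix(dense, c("geneA", "geneB", "MT-CO1"), c("c1", "c2"))
  m <- compute_cell_metrics(cm)
  expect_equal(m$n_features, c(2L, 0L))
  expect_equal(m$n_umi, c(10, 0))
  expect_equal(m$percent_mito, c(50, 0))  # all-zero cell: 0/0 -> 0
})

test_that("metrics on random sparse matrices equal the dense recomputation", {
  for (s in 1:5) {
    cm <- random_count_matrix(s)
    m <- compute_cell_metrics(cm)
    dense <- as.matrix(cm$counts)
    expect_equal(m$n_features, apply(dense, 2, function(c) sum(c > 0)),
                 ignore_attr = TRUE)
    expect_equal(m$n_umi, colSums(dense), ignore_attr = TRUE)
    mt <- colSums(dense[cm$is_mito, , drop = FALSE])
    expect_equal(m$percent_mito,
                 ifelse(m$n_umi > 0, 100 * mt / m$n_umi, 0),
                 ignore_attr = TRUE)
  }
})

test_that("QC boundaries are inclusive at 300 features, exclusive at 15,000 UMI and 10% mito", {
  cm <- boundary_fixture()
  res <- apply_qc(cm)
  expect_setequal(res$filtered$barcodes, c("BC1", "BC4", "BC5", "BC6"))
  expect_false("RARE1" %in% res$filtered$gene_ids)
  rep <- res$report
  expect_equal(rep$cells_removed_high_umi, 1)
  expect_equal(rep$cells_removed_high_mito, 1)
  expect_equal(rep$cells_removed_low_features, 0)
  expect_equal(rep$genes_removed, sum(rowSums(as.matrix(cm$counts) > 0) < 3))
})

test_that("QC filter equals the brute-force oracle on random matrices", {
  for (s in 1:30) {
    cm <- random_count_matrix(s, n_genes = 350, n_cells = 25)
    res <- apply_qc(cm)
    want <- oracle_qc(as.matrix(cm$counts), cm$gene_ids, cm$is_mito)
    expect_identical(res$filtered$barcodes, cm$barcodes[want$cell_keep])
    expect_identical(res$filtered$gene_ids, cm$gene_ids[want$gene_keep])
    # report arithmetic: before - removed = after, per rule family
    rep <- res$report
    expect_equal(rep$cells_before - rep$cells_removed_low_features -
                   rep$cells_removed_high_umi - rep$cells_removed_high_mito,
                 rep$cells_after)
    expect_equal(rep$genes_before - rep$genes_removed, rep$genes_after)
  }
})

test_that("QC survivors are invariant under row/column permutation", {
  cm <- simulate_count_matrix(matrix_sim_params(n_genes = 500L, n_cells = 60L,
                                                n_low_feature = 2L,
                                                n_high_mito = 1L, seed = 5))
  set.seed(99)
  pg <- sample(length(cm$gene_ids)); pc <- sample(length(cm$barcodes))
  perm <- count_matrix(cm$counts[pg, pc], cm$gene_ids[pg], cm$barcodes[pc])
  a <- apply_qc(cm); b <- apply_qc(perm)
  expect_setequal(a$filtered$barcodes, b$filtered$barcodes)
  expect_setequal(a$filtered$gene_ids, b$filtered$gene_ids)
})

test_that("emptying filters warn instead of erroring", {
  dense <- matrix(1, 10, 4)  # 10 features each, far below 300
  cm <- count_matrix(dense, sprintf("G%d", 1:10), sprintf("c%d", 1:4))
  expect_warning(res <- apply_qc(cm), "removed every")
  expect_equal(res$report$cells_after, 0)
})

test_that("cluster phase summary flags strict G1 dominance", {
  ann <- data.frame(
    cluster = rep(c("c1", "c2", "c3"), times = c(10, 10, 12)),
    phase = c(rep("G1", 9), "S",                  # 0.9 -> flagged
              rep("G1", 8), "S", "G2M",           # 0.8 exactly -> not
              rep(c("G1", "S", "G2M"), 4)))       # 1/3 each
  s <- cluster_phase_summary(ann)
  expect_equal(s$frac_G1[s$cluster == "c1"], 0.9)
  expect_true(s$g1_dominant[s$cluster == "c1"])
  expect_equal(s$frac_G1[s$cluster == "c2"], 0.8)
  expect_false(s$g1_dominant[s$cluster == "c2"])
  expect_equal(s$frac_G1 + s$frac_S + s$frac_G2M, rep(1, 3))
  expect_error(cluster_phase_summary(data.frame(cluster = 1, phase = "M")),
               "unknown cell-cycle phase")
})

test_that("phase fractions equal a brute-force tally on random labels", {
  set.seed(8)
  ann <- data.frame(cluster = sample(paste0("k", 1:6), 500, replace = TRUE),
                    phase = sample(c("G1", "S", "G2M"), 500, replace = TRUE))
  s <- cluster_phase_summary(ann)
  for (k in s$cluster) {
    sub <- ann[ann$cluster == k, ]
    expect_equal(s$n_cells[s$cluster == k], nrow(sub))
    expect_equal(s$frac_G1[s$cluster == k], mean(sub$phase == "G1"))
    expect_equal(s$frac_S[s$cluster == k], mean(sub$phase == "S"))
  }
})

test_that("composition ratio counts mapped lineages", {
  ann <- data.frame(cluster = rep(c("a", "b"), c(55, 50)))
  map <- c(a = "neuronal", b = "glial")
  expect_equal(as.numeric(composition_ratio(ann, "neuronal", "glial", map)), 1.1)
  expect_equal(as.numeric(composition_ratio(ann, "glial", "glial", map)), 1)
  even <- data.frame(lineage = rep(c("glial", "neuronal"), each = 50),
                     cluster = "x")
  expect_equal(as.numeric(composition_ratio(even, "glial", "neuronal")), 1)
  # unmapped cluster -> counted as other, with warning
  ann2 <- data.frame(cluster = c(rep("a", 5), rep("z", 3), rep("b", 5)))
  expect_warning(r <- composition_ratio(ann2, "neuronal", "glial", map),
                 "absent from lineage map")
  expect_equal(as.numeric(r), 1)
  expect_error(composition_ratio(ann, "neuronal", "stem", map),
               "undefined ratio")
})

test_that("MatrixMarket triplets roundtrip with orientation detection", {
  cm <- simulate_count_matrix(matrix_sim_params(n_genes = 320L, n_cells = 12L,
                                                seed = 2))
  d <- withr::local_tempdir()
  write_count_matrix(cm, d)
  back <- read_count_matrix(d)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts),
               ignore_attr = TRUE)
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_identical(back$barcodes, cm$barcodes)
  # transpose on disk: reader flips cells x genes back to genes x cells
  d2 <- withr::local_tempdir()
  Matrix::writeMM(Matrix::t(cm$counts), file.path(d2, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(d2, "features.tsv"))
  writeLines(cm$barcodes, file.path(d2, "barcodes.tsv"))
  expect_message(back2 <- read_count_matrix(d2), "transposing")
  expect_equal(as.matrix(back2$counts), as.matrix(cm$counts),
               ignore_attr = TRUE)
})
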