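make_hand_table <- function() {
  # 2 groups x 2 bio reps, one target, two references, one tech rep;
  # target is 2 cycles lower (4x expression) in group B
  genes <- c("T1", "R1", "R2")
  rows <- expand.grid(gene = genes, group = c("A", "B"), bio_rep = 1:2,
                      stringsAsFactors = FALSE)
  rows$sample <- paste0(rows$group, rows$bio_rep)
  rows$tech_rep <- 1L
  rows$ct <- ifelse(rows$gene == "T1", ifelse(rows$group == "B", 20, 22),
                    ifelse(rows$gene == "R1", 18, 19))
  ct_table(rows, reference_genes = c("R1", "R2"))
}

test_that("delta-delta-Ct reproduces the hand calculation", {
  tab <- make_hand_table()
  expr <- delta_delta_ct(tab, calibrator = "A")
  s <- expr$summary
  expect_equal(s$minus_ddct[s$gene == "T1" & s$group == "A"], 0)
  expect_equal(s$fold_change[s$gene == "T1" & s$group == "A"], 1)
  expect_equal(s$minus_ddct[s$gene == "T1" & s$group == "B"], 2)
  expect_equal(s$fold_change[s$gene == "T1" & s$group == "B"], 4)
})

test_that("a global per-sample Ct shift leaves dCt bit-identical", {
  tab <- make_hand_table()
  shifted <- tab
  one <- shifted$sample == "B1"
  shifted$ct[one] <- shifted$ct[one] + 1  # loading effect on every gene
  e1 <- delta_delta_ct(tab, calibrator = "A")
  e2 <- delta_delta_ct(ct_table(shifted, c("R1", "R2")), calibrator = "A")
  expect_identical(e1$summary$minus_ddct, e2$summary$minus_ddct)
  expect_identical(e1$per_sample$dct, e2$per_sample$dct)
})

test_that("delta-delta-Ct validates its inputs", {
  tab <- make_hand_table()
  expect_error(delta_delta_ct(tab, references = character(0)), "no reference")
  expect_warning(delta_delta_ct(tab, references = "R1", calibrator = "A"),
                 "single reference")
  expect_error(delta_delta_ct(tab, calibrator = "Z"), "not present")
  no_cal <- tab[!(tab$gene == "T1" & tab$group == "A"), ]
  expect_error(delta_delta_ct(ct_table(no_cal, c("R1", "R2")), calibrator = "A"),
               "absent in calibrator")
  expect_error(ct_table(data.frame(gene = "g", ct = 1)), "missing column")
  bad <- tab; bad$ct[1] <- -1
  expect_error(ct_table(as.data.frame(bad), c("R1", "R2")), "finite and > 0")
})

test_that("planted fold changes are recovered from noisy tables", {
  est <- vapply(1:40, function(s) {
    tab <- simulate_ct_table(ct_sim_params(genes = "PAX6",
                                           true_log2fc = list(PAX6 = c(p25 = 1.5)),
                                           ct_noise_sd = 0.2, n_bio_reps = 3,
                                           n_tech_reps = 3, seed = s))
    e <- delta_delta_ct(tab, calibrator = "p5")
    e$summary$minus_ddct[e$summary$gene == "PAX6" & e$summary$group == "p25"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.1)
  expect_lt(mean(abs(est - 1.5)), 0.2)
})

test_that("geNorm M is zero for co-varying candidates and matches the oracle", {
  # two candidates whose Ct difference is constant across samples
  co <- hand_ct_table(data.frame(
    gene = rep(c("H1", "H2"), 4),
    sample = rep(paste0("s", 1:4), each = 2),
    group = "A",
    ct = rep(c(20, 23), 4) + rep(rnorm(4), each = 2)))
  rank0 <- reference_stability(co, c("H1", "H2"))
  expect_equal(rank0$M, c(0, 0))
  # random tables: implementation (Ct differences) vs oracle (2^-Ct ratios)
  for (s in 1:10) {
    set.seed(s)
    genes <- c("A1", "B2", "C3", "D4")
    tab <- hand_ct_table(expand.grid(gene = genes, sample = paste0("s", 1:6),
                                     group = "A", stringsAsFactors = FALSE))
    tab$ct <- runif(nrow(tab), 18, 30)
    got <- reference_stability(tab, genes)
    want <- oracle_genorm_m(ct_matrix_of(tab, genes))
    expect_equal(setNames(got$M, got$gene), want[got$gene])
  }
})

test_that("geNorm M is permutation- and shift-invariant", {
  set.seed(31)
  genes <- c("G1", "G2", "G3", "G4", "G5")
  tab <- hand_ct_table(expand.grid(gene = genes, sample = paste0("s", 1:8),
                                   group = "A", stringsAsFactors = FALSE))
  tab$ct <- runif(nrow(tab), 16, 32)
  a <- reference_stability(tab, genes)
  b <- reference_stability(tab, rev(genes))
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)
  # global per-sample shift cancels in every pairwise ratio
  shifted <- tab
  shifts <- setNames(rnorm(8, 0, 2), paste0("s", 1:8))
  shifted$ct <- shifted$ct + shifts[shifted$sample]
  c <- reference_stability(shifted, genes)
  expect_equal(a$M[order(a$gene)], c$M[order(c$gene)])
})

test_that("reference stability errors on a candidate missing from a sample", {
  tab <- make_hand_table()
  gap <- tab[!(tab$gene == "R2" & tab$sample == "B1"), ]
  expect_error(reference_stability(gap, c("R1", "R2")), "R2.*B1")
  expect_error(reference_stability(tab, "R1"), "two candidate")
})

test_that("Welch comparison of expression matches the oracle and flags n<2", {
  tab <- simulate_ct_table(ct_sim_params(genes = "GFAP",
                                         true_log2fc = list(GFAP = c(p25 = 2)),
                                         ct_noise_sd = 0.3, n_bio_reps = 4,
                                         n_tech_reps = 2, seed = 17))
  expr <- delta_delta_ct(tab, calibrator = "p5")
  cmp <- welch_compare(expr, "GFAP", c("p25", "p5"))
  ps <- expr$per_sample
  want <- oracle_welch(ps$minus_ddct[ps$gene == "GFAP" & ps$group == "p25"],
                       ps$minus_ddct[ps$gene == "GFAP" & ps$group == "p5"])
  expect_equal(cmp$statistic, want$t)
  expect_equal(cmp$df, want$df)
  expect_equal(cmp$p_value, want$p)
  # identical replicate sets -> t = 0
  ident <- welch_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  # a single biological replicate cannot be tested
  tab1 <- simulate_ct_table(ct_sim_params(genes = "GFAP", n_bio_reps = 1,
                                          seed = 1))
  e1 <- delta_delta_ct(tab1, calibrator = "p5")
  c1 <- welch_compare(e1, "GFAP", c("p25", "p5"))
  expect_false(c1$computable)
})
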