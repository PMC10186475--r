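# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: per-pixel loops instead of histograms,
# dense loops instead of sparse ops, textbook formulas instead of stats::.

# Per-pixel sum of squared brightness (the definition the histogram route
# must reproduce exactly).
oracle_index <- function(pixels) {
  s <- 0
  for (v in as.vector(pixels)) s <- s + as.numeric(v)^2
  s
}

# Textbook Welch t statistic, Welch-Satterthwaite df, two-sided p.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# geNorm pairwise-stability M computed on linear relative quantities
# Q = 2^(-Ct), as the definition states (the implementation works on Ct
# differences instead).
oracle_genorm_m <- function(ct_matrix) {
  q <- 2^(-ct_matrix)
  genes <- rownames(ct_matrix)
  vapply(genes, function(j) {
    others <- setdiff(genes, j)
    mean(vapply(others, function(k) sd(log2(q[j, ] / q[k, ])), numeric(1)))
  }, numeric(1))
}

# Technically-averaged Ct matrix (candidates x samples) from a long table.
ct_matrix_of <- function(table, genes) {
  samples <- sort(unique(table$sample))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (g in genes) for (s in samples)
    m[g, s] <- mean(table$ct[table$gene == g & table$sample == s])
  m
}

# Brute-force QC filter written directly from the stated rules, on a dense
# matrix with explicit per-cell loops.
oracle_qc <- function(dense, gene_ids, is_mito, th = qc_thresholds()) {
  ng <- nrow(dense); nc <- ncol(dense)
  gene_keep <- logical(ng)
  for (g in seq_len(ng))
    gene_keep[g] <- sum(dense[g, ] > 0) >= th$min_cells_per_gene
  cell_keep <- logical(nc)
  for (j in seq_len(nc)) {
    col <- dense[, j]
    nf <- sum(col > 0)
    umi <- sum(col)
    mt <- sum(col[is_mito])
    pct <- if (umi > 0) 100 * mt / umi else 0
    cell_keep[j] <- nf >= th$min_features_per_cell &&
      umi < th$max_umi_per_cell && pct < th$max_mito_percent
  }
  list(gene_keep = gene_keep, cell_keep = cell_keep)
}

# Small random count_matrix for oracle-equivalence sweeps; thresholds are
# passed alongside so tiny matrices can be stressed against the stated
# (fixed) rule set.
random_count_matrix <- function(seed, n_genes = 400, n_cells = 40) {
  set.seed(seed)
  dense <- matrix(rpois(n_genes * n_cells, 0.9) *
                    (runif(n_genes * n_cells) < 0.8), n_genes, n_cells)
  # sprinkle structure: some dense cells, some heavy cells, some mito load
  heavy <- sample.int(n_cells, 3)
  dense[, heavy] <- dense[, heavy] + rpois(n_genes * 3, 2)
  ids <- c(sprintf("MT-%02d", 1:5), sprintf("G%04d", seq_len(n_genes - 5)))
  mito_cells <- sample.int(n_cells, 2)
  dense[1:5, mito_cells] <- dense[1:5, mito_cells] + rpois(10, 30)
  count_matrix(dense, ids, sprintf("BC%04d", seq_len(n_cells)))
}

# Deterministic boundary fixture: 400 genes x 6 cells.
#   cell 1: exactly 300 detected genes      -> kept  ("at least 300")
#   cell 2: exactly 15,000 UMI              -> removed (strict "< 15,000")
#   cell 3: exactly 10% mitochondrial       -> removed (strict "< 10%")
#   cells 4-6: comfortable baseline cells
#   gene 400 ("RARE1"): detected in exactly 2 cells -> removed ("at least 3")
boundary_fixture <- function() {
  ng <- 400L
  ids <- c(sprintf("MT-%02d", 1:4), sprintf("G%04d", 1:(ng - 5)), "RARE1")
  dense <- matrix(0, ng, 6)
  dense[5:304, 1] <- 1                      # 300 features, no mito
  dense[5:304, 2] <- 50                     # 300 features, 15,000 UMI exactly
  dense[5:364, 3] <- 1                      # 360 features...
  dense[1:4, 3] <- 10                       # ...plus 40 mito of 400 = 10%
  dense[5:364, 4:6] <- 2
  dense[1:4, 4:6] <- 1                      # mito ~0.55% in baseline cells
  dense[ng, c(4, 5)] <- 1                   # RARE1 in exactly 2 cells
  count_matrix(dense, ids, sprintf("BC%d", 1:6))
}

tiny_image_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(width = 64L, height = 64L, n_cells = 10L,
                                 nucleus_sigma = 2.5, seed = seed),
                            list(...))
  do.call(image_sim_params, args)
}

uniform_pair <- function(marker_value, nuclei_value, n = 8, bit_depth = 8L) {
  image_pair(fluor_image(matrix(as.integer(marker_value), n, n), bit_depth, "marker"),
             fluor_image(matrix(as.integer(nuclei_value), n, n), bit_depth, "nuclei"))
}

# Long-format Ct table built by hand (one tech rep unless given).
hand_ct_table <- function(df) {
  df$bio_rep <- df$bio_rep %||% 1L
  df$tech_rep <- df$tech_rep %||% 1L
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
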