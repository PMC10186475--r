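# Single-cell QC filtering and cluster-level summaries.
#
# Filters applied to a raw genes x cells UMI matrix, in two stages:
#   stage 1 (jointly, on the raw matrix): keep genes detected in >= 3 cells
#     and cells with >= 300 detected genes;
#   stage 2 (on surviving cells, metrics from the raw matrix): keep cells
#     with total UMI < 15,000 and mitochondrial percentage < 10.
# Cluster summaries consume externally produced per-cell annotations
# (cluster id, cell-cycle phase, lineage class): phase occupancy with a
# strict >80% G1-dominance flag, and lineage composition ratios such as
# glia:neuron.

#' Construct a sparse gene x cell count matrix
#'
#' @param counts genes x cells matrix (coerced to sparse `dgCMatrix`);
#'   nonnegative integers.
#' @param gene_ids,barcodes id vectors matching the dimensions.
#' @param mito_pattern regex (case-insensitive) identifying mitochondrial
#'   genes by name; the conventional human prefix `MT-` by default.
#' @param mito_genes optional explicit character vector overriding the
#'   pattern.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes, mito_pattern = "^MT-",
                         mito_genes = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (methods::is(counts, "lMatrix") || methods::is(counts, "nMatrix"))
    counts <- methods::as(counts, "dMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(barcodes))
    stop("dimensions do not match gene/barcode id lists")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  dimnames(counts) <- list(gene_ids, barcodes)
  mito <- if (!is.null(mito_genes)) gene_ids %in% mito_genes
          else grepl(mito_pattern, gene_ids, ignore.case = TRUE)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 is_mito = mito),
            class = "count_matrix")
}

#' Default QC thresholds
#'
#' The four stated filter parameters: a gene must be expressed in at least
#' 3 cells; a cell must contain at least 300 different genes, fewer than
#' 15,000 UMI (exclusive) and less than 10 percent mitochondrial RNA
#' (exclusive).
#'
#' @param min_cells_per_gene,min_features_per_cell inclusive minima.
#' @param max_umi_per_cell,max_mito_percent exclusive maxima.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L, min_features_per_cell = 300L,
                          max_umi_per_cell = 15000, max_mito_percent = 10) {
  stopifnot(min_cells_per_gene > 0, min_features_per_cell > 0,
            max_umi_per_cell > 0, max_mito_percent > 0)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_features_per_cell = as.integer(min_features_per_cell),
                 max_umi_per_cell = max_umi_per_cell,
                 max_mito_percent = max_mito_percent),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param cm a [count_matrix()].
#' @return data.frame (barcode, n_features, n_umi, percent_mito); an
#'   all-zero cell has `percent_mito = 0` by convention (it fails the
#'   feature rule regardless).
#' @export
compute_cell_metrics <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  n_umi <- Matrix::colSums(m)
  n_features <- Matrix::colSums(m > 0)
  mito_counts <- if (any(cm$is_mito))
    Matrix::colSums(m[cm$is_mito, , drop = FALSE]) else rep(0, ncol(m))
  pct <- ifelse(n_umi > 0, 100 * mito_counts / n_umi, 0)
  data.frame(barcode = cm$barcodes, n_features = as.integer(n_features),
             n_umi = as.numeric(n_umi), percent_mito = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Apply the QC filters to a count matrix
#'
#' Stage 1 evaluates the gene rule (detected in at least
#' `min_cells_per_gene` cells) and the cell feature rule (at least
#' `min_features_per_cell` detected genes) jointly on the raw matrix in a
#' single pass, mirroring the creation-time semantics of the stated
#' parameters (no iterative re-evaluation). Stage 2 then keeps surviving
#' cells with `n_umi < max_umi_per_cell` and
#' `percent_mito < max_mito_percent`, both computed on the raw matrix.
#'
#' @param cm a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list: `filtered` (a `count_matrix`), `report` (a `qc_report`
#'   with before/after counts per rule and the per-cell metrics table).
#'   An empty result is returned with a warning, not an error.
#' @export
apply_qc <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  m <- cm$counts
  metrics <- compute_cell_metrics(cm)
  cells_per_gene <- Matrix::rowSums(m > 0)
  gene_keep <- cells_per_gene >= thresholds$min_cells_per_gene
  feat_keep <- metrics$n_features >= thresholds$min_features_per_cell
  umi_keep <- metrics$n_umi < thresholds$max_umi_per_cell
  mito_keep <- metrics$percent_mito < thresholds$max_mito_percent
  cell_keep <- feat_keep & umi_keep & mito_keep
  # disjoint attribution: a removed cell is charged to the first rule
  # (features, then UMI, then mito) that rejects it
  removed_by <- ifelse(!feat_keep, "low_features",
                ifelse(!umi_keep, "high_umi",
                ifelse(!mito_keep, "high_mito", "kept")))
  filtered <- count_matrix(m[gene_keep, cell_keep, drop = FALSE],
                           cm$gene_ids[gene_keep], cm$barcodes[cell_keep],
                           mito_genes = cm$gene_ids[cm$is_mito])
  report <- structure(list(
    thresholds = thresholds,
    genes_before = nrow(m), genes_after = sum(gene_keep),
    genes_removed = sum(!gene_keep),
    cells_before = ncol(m), cells_after = sum(cell_keep),
    cells_removed_low_features = sum(removed_by == "low_features"),
    cells_removed_high_umi = sum(removed_by == "high_umi"),
    cells_removed_high_mito = sum(removed_by == "high_mito"),
    metrics = metrics,
    removed_by = setNames(removed_by, cm$barcodes)),
    class = "qc_report")
  if (report$cells_after == 0 || report$genes_after == 0)
    warning("QC filtering removed every ",
            if (report$cells_after == 0) "cell" else "gene")
  list(filtered = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Single-cell QC report\n")
  cat(sprintf("  genes: %d -> %d (%d detected in < %d cells)\n",
              x$genes_before, x$genes_after, x$genes_removed,
              x$thresholds$min_cells_per_gene))
  cat(sprintf("  cells: %d -> %d\n", x$cells_before, x$cells_after))
  cat(sprintf("    removed: %d with < %d features, %d with >= %s UMI, %d with >= %s%% mito\n",
              x$cells_removed_low_features, x$thresholds$min_features_per_cell,
              x$cells_removed_high_umi, format(x$thresholds$max_umi_per_cell),
              x$cells_removed_high_mito, format(x$thresholds$max_mito_percent)))
  invisible(x)
}

PHASE_LEVELS <- c("G1", "S", "G2M")

#' Per-cluster cell-cycle phase occupancy with G1-dominance flag
#'
#' Consumes an externally produced annotation table and tallies, per
#' cluster, the fraction of cells in each phase. A cluster is flagged
#' `g1_dominant` when strictly more than 80 percent of its cells are in G1
#' (exactly 80 percent is not flagged); such clusters are interpreted as
#' terminally differentiating populations.
#'
#' @param annotations data.frame with columns `barcode` (optional),
#'   `cluster`, `phase` (one of `"G1"`, `"S"`, `"G2M"`).
#' @param g1_threshold dominance threshold on the G1 fraction (strict).
#' @return data.frame: cluster, n_cells, frac_G1, frac_S, frac_G2M,
#'   g1_dominant.
#' @export
cluster_phase_summary <- function(annotations, g1_threshold = 0.8) {
  stopifnot(all(c("cluster", "phase") %in% names(annotations)))
  bad <- setdiff(unique(annotations$phase), PHASE_LEVELS)
  if (length(bad))
    stop("unknown cell-cycle phase label(s): ", paste(bad, collapse = ", "))
  tab <- table(cluster = annotations$cluster,
               phase = factor(annotations$phase, levels = PHASE_LEVELS))
  n <- rowSums(tab)
  frac <- tab / n
  out <- data.frame(cluster = rownames(tab), n_cells = as.integer(n),
                    frac_G1 = as.numeric(frac[, "G1"]),
                    frac_S = as.numeric(frac[, "S"]),
                    frac_G2M = as.numeric(frac[, "G2M"]),
                    stringsAsFactors = FALSE)
  out$g1_dominant <- out$frac_G1 > g1_threshold
  out
}

#' Lineage composition ratio (e.g. glia : neurons)
#'
#' Counts annotated cells by lineage class, mapping clusters through
#' `lineage_map` when per-cell lineage is absent, and returns the
#' numerator:denominator cell-count ratio. Cells of clusters missing from
#' the map are counted as `"other"` (with a warning) and excluded.
#'
#' @param annotations data.frame with `cluster` and optionally `lineage`.
#' @param numerator,denominator lineage class names (e.g. `"glial"`,
#'   `"neuronal"`).
#' @param lineage_map named character vector cluster -> lineage class; used
#'   when the table has no `lineage` column.
#' @return scalar ratio, with the per-class counts as attribute `counts`.
#' @export
composition_ratio <- function(annotations, numerator = "glial",
                              denominator = "neuronal", lineage_map = NULL) {
  lin <- if ("lineage" %in% names(annotations) && is.null(lineage_map)) {
    as.character(annotations$lineage)
  } else {
    if (is.null(lineage_map)) stop("need a lineage column or a lineage_map")
    cl <- as.character(annotations$cluster)
    unmapped <- setdiff(unique(cl), names(lineage_map))
    if (length(unmapped)) {
      warning("cluster(s) absent from lineage map counted as 'other': ",
              paste(unmapped, collapse = ", "))
    }
    out <- unname(lineage_map[cl])
    out[is.na(out)] <- "other"
    out
  }
  counts <- table(lin)
  den <- if (denominator %in% names(counts)) counts[[denominator]] else 0L
  if (den == 0) stop("undefined ratio: no cells in denominator class '",
                     denominator, "'")
  num <- if (numerator %in% names(counts)) counts[[numerator]] else 0L
  structure(num / den, counts = counts)
}

#' Read a 10x-style MatrixMarket directory into a count matrix
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`
#' (optionally gzipped). Orientation is auto-detected from the id-file
#' lengths: if matrix rows match the barcode count instead of the feature
#' count, the matrix is transposed to genes x cells and a message records
#' the decision.
#'
#' @param dir directory containing the triplet.
#' @param ... passed to [count_matrix()] (e.g. `mito_pattern`).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(dir, ...) {
  find1 <- function(names) {
    for (nm in names) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(nm, ext))
      if (file.exists(p)) return(p)
    }
    stop("no ", names[1], " found in ", dir)
  }
  m <- methods::as(Matrix::readMM(find1("matrix.mtx")), "CsparseMatrix")
  feats <- read.delim(find1(c("features.tsv", "genes.tsv")), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- read.delim(find1("barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(m) != length(gene_ids) && nrow(m) == length(barcodes) &&
      ncol(m) == length(gene_ids)) {
    message("matrix stored cells x genes; transposing to genes x cells")
    m <- Matrix::t(m)
  }
  count_matrix(m, gene_ids, barcodes, ...)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cm$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
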