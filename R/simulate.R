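# Synthetic-data generators.
#
# Every input class the pipeline consumes can be generated with known ground
# truth: two-channel fluorescence fields (Gaussian-blob nuclei, a
# controllable marker-positive fraction, camera-style noise), qPCR Ct tables
# with planted log2 fold changes and reference-gene stability structure,
# sparse UMI matrices with planted violations of each QC rule, and
# exponential-growth passage counts. All generators are pure functions of
# (params, seed).

#' Parameters for the two-channel image simulator
#'
#' Defaults describe a plausible 16-bit widefield field of view: 512 x 512
#' pixels, ~150 nuclei of sigma 5 px rendered as isotropic Gaussian blobs,
#' moderate background and read noise, Poisson shot noise on.
#'
#' @param width,height image size in pixels.
#' @param bit_depth 8 or 16.
#' @param n_cells number of nuclei.
#' @param nucleus_sigma Gaussian sigma of a nucleus, pixels.
#' @param nucleus_amplitude peak nuclear (DAPI) intensity above background.
#' @param positive_fraction fraction of cells positive for the marker, in
#'   `[0, 1]`; `round(positive_fraction * n_cells)` cells are positive.
#' @param marker_amplitude peak marker intensity of a positive cell.
#' @param background_level constant background added to both channels.
#' @param read_noise_sd sd of additive Gaussian read noise.
#' @param shot_noise apply Poisson shot noise to the noiseless signal.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 512L, height = 512L, bit_depth = 16L,
                             n_cells = 150L, nucleus_sigma = 5,
                             nucleus_amplitude = 3000,
                             positive_fraction = 0.3,
                             marker_amplitude = 2000,
                             background_level = 200, read_noise_sd = 20,
                             shot_noise = TRUE, seed = 1L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            bit_depth = as.integer(bit_depth), n_cells = as.integer(n_cells),
            nucleus_sigma = nucleus_sigma,
            nucleus_amplitude = nucleus_amplitude,
            positive_fraction = positive_fraction,
            marker_amplitude = marker_amplitude,
            background_level = background_level,
            read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
            seed = as.integer(seed))
  if (p$width <= 0 || p$height <= 0) stop("image dimensions must be positive")
  if (!p$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (p$positive_fraction < 0 || p$positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  if (p$nucleus_amplitude < 0 || p$marker_amplitude < 0 ||
      p$background_level < 0 || p$read_noise_sd < 0)
    stop("amplitudes, background and noise sd must be >= 0")
  class(p) <- "image_sim_params"
  p
}

# Draw n centers uniformly, rejecting any closer than min_dist to an
# accepted center; gives approximately non-overlapping nuclei. Falls back to
# accepting after a bounded number of rejections so dense fields terminate.
place_centers <- function(n, width, height, min_dist) {
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  max_tries <- 200L
  while (placed < n) {
    tries <- 0L
    repeat {
      x <- runif(1, 1, width); y <- runif(1, 1, height)
      if (placed == 0L || tries >= max_tries ||
          min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= min_dist^2)
        break
      tries <- tries + 1L
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  data.frame(x = xs, y = ys)
}

# Add an isotropic Gaussian blob to `img` in place (windowed at 4 sigma).
add_blob <- function(img, cx, cy, sigma, amplitude) {
  if (amplitude <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  dy2 <- (rows - cy)^2; dx2 <- (cols - cx)^2
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img
}

# Camera model: optional Poisson shot noise on the noiseless signal, then
# additive Gaussian read noise, then clip and quantize to bit depth.
render_channel <- function(signal, params) {
  if (params$shot_noise) {
    v <- as.vector(signal)
    signal <- matrix(rpois(length(v), pmax(v, 0)), nrow = nrow(signal))
  }
  if (params$read_noise_sd > 0)
    signal <- signal + rnorm(length(signal), 0, params$read_noise_sd)
  maxv <- 2^params$bit_depth - 1
  storage.mode(signal) <- "double"
  m <- matrix(as.integer(pmin(pmax(round(signal), 0), maxv)),
              nrow = nrow(signal))
  m
}

#' Simulate one marker/DAPI image pair with ground truth
#'
#' Nuclei are isotropic Gaussian blobs at centers rejected closer than
#' `2 * nucleus_sigma`; marker-positive cells reuse nucleus centers with a
#' larger (2x sigma) footprint, approximating cytoplasmic staining. Noise:
#' optional Poisson shot noise, then Gaussian read noise, then clip and
#' quantization to bit depth. `control = TRUE` forces the marker amplitude
#' to zero (background plus noise only), modelling staining without the
#' primary antibody.
#'
#' @param params an [image_sim_params()] object.
#' @param control simulate a secondary-only negative control.
#' @param meta optional named list merged into the pair metadata.
#' @return an [image_pair()]; ground truth (cell centers and positivity
#'   labels) is attached as attribute `truth`, and attribute
#'   `expect_saturation` flags parameter sets whose noiseless peak exceeds
#'   the dynamic range.
#' @export
simulate_image_pair <- function(params = image_sim_params(), control = FALSE,
                                meta = list()) {
  stopifnot(inherits(params, "image_sim_params"))
  marker_amp <- if (control) 0 else params$marker_amplitude
  maxv <- 2^params$bit_depth - 1
  expect_sat <- max(params$nucleus_amplitude, marker_amp) +
    params$background_level > maxv
  if (expect_sat)
    warning("amplitude + background exceed the dynamic range: saturation expected")
  pair <- with_seed(params$seed, {
    centers <- place_centers(params$n_cells, params$width, params$height,
                             2 * params$nucleus_sigma)
    n_pos <- round(params$positive_fraction * params$n_cells)
    positive <- rep(FALSE, params$n_cells)
    if (params$n_cells > 0 && n_pos > 0)
      positive[sample.int(params$n_cells, n_pos)] <- TRUE
    nuc <- matrix(params$background_level, params$height, params$width)
    mk <- matrix(params$background_level, params$height, params$width)
    for (i in seq_len(params$n_cells)) {
      nuc <- add_blob(nuc, centers$x[i], centers$y[i], params$nucleus_sigma,
                      params$nucleus_amplitude)
      if (positive[i])
        mk <- add_blob(mk, centers$x[i], centers$y[i],
                       2 * params$nucleus_sigma, marker_amp)
    }
    nuc_px <- render_channel(nuc, params)
    mk_px <- render_channel(mk, params)
    p <- image_pair(fluor_image(mk_px, params$bit_depth, "marker"),
                    fluor_image(nuc_px, params$bit_depth, "nuclei"),
                    line = meta$line %||% NA_character_,
                    passage = meta$passage %||% NA_integer_,
                    marker_name = meta$marker_name %||% NA_character_,
                    bio_rep = meta$bio_rep %||% NA_integer_,
                    tech_rep = meta$tech_rep %||% NA_integer_,
                    is_control = control)
    attr(p, "truth") <- cbind(centers, positive = positive)
    p
  })
  attr(pair, "expect_saturation") <- expect_sat
  pair
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters for the qPCR Ct-table simulator
#'
#' Encoding convention: one threshold cycle equals one doubling (perfect
#' amplification efficiency), so a planted log2 fold change of `L` in a
#' group lowers that group's Ct by `L` cycles relative to the calibrator.
#'
#' @param genes character vector of target gene ids.
#' @param reference_genes character vector of reference (housekeeping) ids.
#' @param groups character vector of group labels (first = calibrator);
#'   at least two.
#' @param true_log2fc named list: per target gene, a named numeric vector of
#'   planted log2 fold changes per non-calibrator group (0 if absent).
#'   Reference genes always have 0.
#' @param base_ct named numeric of baseline Ct per gene (default 24 for
#'   targets, 20 for references).
#' @param ct_noise_sd sd of replicate-level Gaussian Ct noise, cycles.
#' @param stability_sd named numeric: per-gene sd of an extra per-sample
#'   Ct wobble, the stability perturbation used to make some candidate
#'   references less stable than others (default 0 for all).
#' @param sample_shift_sd sd of a per-sample global Ct shift applied to all
#'   genes (loading/pipetting effect; cancels under normalization).
#' @param n_bio_reps,n_tech_reps replicate counts per group.
#' @param seed integer seed.
#' @return list of class `ct_sim_params`.
#' @export
ct_sim_params <- function(genes = c("PAX6", "GFAP", "TUBB3"),
                          reference_genes = c("EMC7", "PSMB4"),
                          groups = c("p5", "p25"),
                          true_log2fc = list(),
                          base_ct = NULL, ct_noise_sd = 0.2,
                          stability_sd = NULL, sample_shift_sd = 0,
                          n_bio_reps = 2L, n_tech_reps = 3L, seed = 1L) {
  if (length(reference_genes) < 1) stop("need at least one reference gene")
  if (length(groups) < 2) stop("need at least two groups")
  if (n_bio_reps < 1 || n_tech_reps < 1) stop("replicate counts must be >= 1")
  all_genes <- union(genes, reference_genes)
  if (is.null(base_ct))
    base_ct <- setNames(ifelse(all_genes %in% reference_genes, 20, 24), all_genes)
  if (is.null(stability_sd)) stability_sd <- setNames(rep(0, length(all_genes)), all_genes)
  structure(list(genes = genes, reference_genes = reference_genes,
                 groups = groups, true_log2fc = true_log2fc,
                 base_ct = base_ct, ct_noise_sd = ct_noise_sd,
                 stability_sd = stability_sd,
                 sample_shift_sd = sample_shift_sd,
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 seed = as.integer(seed)),
            class = "ct_sim_params")
}

planted_log2fc <- function(params, gene, group) {
  if (gene %in% params$reference_genes) return(0)
  if (group == params$groups[1]) return(0)
  v <- params$true_log2fc[[gene]]
  if (is.null(v)) return(0)
  if (!is.null(names(v))) {
    if (group %in% names(v)) unname(v[[group]]) else 0
  } else as.numeric(v)[1]
}

#' Simulate a long-format qPCR Ct table with planted effects
#'
#' Ct = base_ct(gene) - planted log2fc(gene, group) + per-sample global
#' shift + per-sample stability wobble(gene) + replicate noise. Ground
#' truth (the planted log2 fold changes) is attached as attribute `truth`.
#'
#' @param params a [ct_sim_params()] object.
#' @return data.frame of class `ct_table` with columns gene, sample, group,
#'   bio_rep, tech_rep, ct, and attribute `reference_genes`.
#' @export
simulate_ct_table <- function(params = ct_sim_params()) {
  stopifnot(inherits(params, "ct_sim_params"))
  all_genes <- union(params$genes, params$reference_genes)
  with_seed(params$seed, {
    rows <- list(); k <- 0L
    truth <- list()
    for (g in params$groups) for (b in seq_len(params$n_bio_reps)) {
      sample_id <- sprintf("%s_b%d", g, b)
      shift <- if (params$sample_shift_sd > 0) rnorm(1, 0, params$sample_shift_sd) else 0
      wobble <- rnorm(length(all_genes), 0, params$stability_sd[all_genes])
      names(wobble) <- all_genes
      for (gene in all_genes) {
        l2fc <- planted_log2fc(params, gene, g)
        mu <- params$base_ct[[gene]] - l2fc + shift + wobble[[gene]]
        for (t in seq_len(params$n_tech_reps)) {
          k <- k + 1L
          rows[[k]] <- data.frame(gene = gene, sample = sample_id, group = g,
                                  bio_rep = b, tech_rep = t,
                                  ct = mu + if (params$ct_noise_sd > 0)
                                    rnorm(1, 0, params$ct_noise_sd) else 0,
                                  stringsAsFactors = FALSE)
        }
        truth[[paste(gene, g, sep = "|")]] <- l2fc
      }
    }
    tab <- do.call(rbind, rows)
    if (any(tab$ct <= 0 | tab$ct > 45))
      warning("simulated Ct values outside the plausible 0-45 cycle range")
    attr(tab, "reference_genes") <- params$reference_genes
    attr(tab, "truth") <- truth
    class(tab) <- c("ct_table", "data.frame")
    tab
  })
}

#' Parameters for the sparse UMI count-matrix simulator
#'
#' Baseline cells satisfy all four QC rules (at least 300 detected genes,
#' fewer than 15,000 UMI, under 10 percent mitochondrial counts) and every
#' non-rare gene is detected in at least 3 cells. Planted violations break
#' exactly one rule each so pass/fail attribution is unambiguous.
#'
#' @param n_genes,n_cells matrix dimensions (genes x cells).
#' @param mito_gene_fraction fraction of genes given `MT-` names.
#' @param n_low_feature cells planted with fewer than 300 detected genes.
#' @param n_high_umi cells planted with at least 15,000 total counts.
#' @param n_high_mito cells planted with at least 10 percent mito counts.
#' @param n_rare_gene genes planted as detected in fewer than 3 cells.
#' @param baseline_features mean detected genes of a baseline cell.
#' @param seed integer seed.
#' @return list of class `matrix_sim_params`.
#' @export
matrix_sim_params <- function(n_genes = 1000L, n_cells = 200L,
                              mito_gene_fraction = 0.013,
                              n_low_feature = 0L, n_high_umi = 0L,
                              n_high_mito = 0L, n_rare_gene = 0L,
                              baseline_features = NULL, seed = 1L) {
  if (is.null(baseline_features))
    baseline_features <- min(600L, as.integer(n_genes) - as.integer(n_rare_gene))
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            mito_gene_fraction = mito_gene_fraction,
            n_low_feature = as.integer(n_low_feature),
            n_high_umi = as.integer(n_high_umi),
            n_high_mito = as.integer(n_high_mito),
            n_rare_gene = as.integer(n_rare_gene),
            baseline_features = as.integer(baseline_features),
            seed = as.integer(seed))
  if (p$n_low_feature + p$n_high_umi + p$n_high_mito > p$n_cells)
    stop("planted cell violations exceed n_cells")
  if (p$n_rare_gene > p$n_genes) stop("planted rare genes exceed n_genes")
  if (p$n_genes < 300L + p$n_rare_gene)
    stop("infeasible: baseline cells need >= 300 detectable non-rare genes")
  if (p$baseline_features < 300L || p$baseline_features > p$n_genes - p$n_rare_gene)
    stop("baseline_features must be in [300, n_genes - n_rare_gene]")
  class(p) <- "matrix_sim_params"
  p
}

#' Simulate a sparse UMI matrix with planted QC violations
#'
#' Returns a genes x cells `dgCMatrix` plus ground-truth pass/fail labels.
#' Planted low-feature cells have 100 detected genes; high-UMI cells at
#' least 15,000 counts; high-mito cells at least 10 percent of counts on
#' `MT-` genes; rare genes are detected in exactly 2 cells (or fewer when
#' planted in an emptier corner). All other cells and genes satisfy every
#' rule by construction (verified, then repaired, before return).
#'
#' @param params a [matrix_sim_params()] object.
#' @return a [count_matrix()] with attributes `cell_truth` and `gene_truth`
#'   (logical: passes all rules).
#' @export
simulate_count_matrix <- function(params = matrix_sim_params()) {
  stopifnot(inherits(params, "matrix_sim_params"))
  with_seed(params$seed, {
    ng <- params$n_genes; nc <- params$n_cells
    n_mito <- max(1L, round(params$mito_gene_fraction * ng))
    gene_ids <- c(sprintf("MT-G%03d", seq_len(n_mito)),
                  sprintf("GENE%05d", seq_len(ng - n_mito)))
    barcodes <- sprintf("CELL%05d-1", seq_len(nc))
    mito_idx <- seq_len(n_mito)
    # reserve the tail genes as the planted rare genes
    rare_idx <- if (params$n_rare_gene > 0)
      (ng - params$n_rare_gene + 1L):ng else integer(0)
    common_idx <- setdiff(seq_len(ng), rare_idx)

    bad_cells <- sample.int(nc, params$n_low_feature + params$n_high_umi +
                              params$n_high_mito)
    low_cells <- head(bad_cells, params$n_low_feature)
    umi_cells <- head(setdiff(bad_cells, low_cells), params$n_high_umi)
    mito_cells <- setdiff(bad_cells, c(low_cells, umi_cells))
    good_cells <- setdiff(seq_len(nc), bad_cells)

    ii <- list(); jj <- list(); xx <- list()
    for (j in seq_len(nc)) {
      if (j %in% low_cells) {
        nf <- 100L
      } else {
        nf <- min(length(common_idx),
                  max(320L, round(rnorm(1, params$baseline_features,
                                        params$baseline_features / 10))))
      }
      genes_j <- sample(common_idx, nf)
      counts_j <- rpois(nf, 4) + 1L
      if (j %in% umi_cells) {
        # inflate uniformly so the cell crosses 15,000 UMI but no other rule
        counts_j <- counts_j + 15500L %/% nf + 1L
      } else {
        # keep baseline totals comfortably below 15,000
        tot <- sum(counts_j)
        if (tot >= 12000L) counts_j <- pmax(1L, counts_j %/% 2L)
      }
      if (j %in% mito_cells) {
        # push mito counts to ~15% of the total, staying under the UMI cap
        tot <- sum(counts_j)
        mito_target <- ceiling(0.15 * tot / (1 - 0.15))
        add <- rep(mito_target %/% n_mito + 1L, n_mito)
        present <- genes_j %in% mito_idx
        counts_j[present] <- counts_j[present] + add[match(genes_j[present], mito_idx)]
        new_m <- setdiff(mito_idx, genes_j)
        genes_j <- c(genes_j, new_m)
        counts_j <- c(counts_j, add[match(new_m, mito_idx)])
      } else if (!(j %in% low_cells)) {
        # cap accidental mito load of baseline/umi cells below 10%
        present <- which(genes_j %in% mito_idx)
        if (length(present)) {
          tot <- sum(counts_j)
          cap <- floor(0.08 * tot / length(present))
          counts_j[present] <- pmin(counts_j[present], max(1L, cap))
        }
      }
      ii[[j]] <- genes_j; jj[[j]] <- rep(j, length(genes_j)); xx[[j]] <- counts_j
    }
    m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = as.numeric(unlist(xx)), dims = c(ng, nc))
    # plant rare genes: detected in exactly min(2, |good_cells|) cells
    for (g in rare_idx) {
      cells <- sample(good_cells, min(2L, length(good_cells)))
      m[g, cells] <- 1
    }
    # repair: every common gene must be detected in >= 3 cells
    det <- Matrix::rowSums(m[common_idx, , drop = FALSE] > 0)
    fixable <- length(good_cells) >= 3L
    for (g in common_idx[det < 3]) {
      if (!fixable) break
      have <- which(m[g, ] > 0)
      need <- 3L - length(have)
      pool <- setdiff(good_cells, have)
      m[g, sample(pool, need)] <- 1
    }
    cm <- count_matrix(m, gene_ids, barcodes)
    cell_truth <- rep(TRUE, nc)
    cell_truth[c(low_cells, umi_cells, mito_cells)] <- FALSE
    gene_truth <- rep(TRUE, ng)
    gene_truth[rare_idx] <- FALSE
    attr(cm, "cell_truth") <- setNames(cell_truth, barcodes)
    attr(cm, "gene_truth") <- setNames(gene_truth, gene_ids)
    cm
  })
}

#' Simulate serial-passage cell counts under exponential growth
#'
#' Each passage seeds a fixed number of cells (default 800,000, a 6 cm dish)
#' and harvests `seeded * 2^(M)` cells with per-passage doublings
#' `M ~ Normal(mean_doublings, sd_doublings)`.
#'
#' @param n_passages number of passages.
#' @param n_seeded cells seeded per passage.
#' @param mean_doublings planted mean doublings per passage.
#' @param sd_doublings passage-to-passage sd of doublings.
#' @param days_in_passage days per passage (constant), or `NULL` to omit.
#' @param line line label.
#' @param seed integer seed.
#' @return data.frame (line, passage, n_seeded, n_grown, days) with the
#'   planted per-passage doublings as attribute `truth`.
#' @export
simulate_growth_series <- function(n_passages = 25L, n_seeded = 800000,
                                   mean_doublings = 2.3, sd_doublings = 0.15,
                                   days_in_passage = 4, line = "NSC-SIM",
                                   seed = 1L) {
  stopifnot(n_passages >= 1, n_seeded > 0)
  with_seed(seed, {
    m_true <- rnorm(n_passages, mean_doublings, sd_doublings)
    grown <- round(n_seeded * 2^m_true)
    out <- data.frame(line = line, passage = seq_len(n_passages),
                      n_seeded = n_seeded, n_grown = grown,
                      days = if (is.null(days_in_passage)) NA_real_ else days_in_passage)
    attr(out, "truth") <- m_true
    out
  })
}

#' Simulate a full image set with manifest
#'
#' Generates stained fields and matched secondary-only controls for a grid
#' of conditions, writes them as per-channel grayscale TIFFs with a manifest
#' CSV, mirroring the acquisition layout of two biological repeats each with
#' two technical repeats.
#'
#' @param out_dir output directory (created).
#' @param base_params an [image_sim_params()]; its seed is the root seed
#'   from which per-field child seeds are derived.
#' @param lines,passages,markers condition grid.
#' @param n_bio,n_tech replicates per condition.
#' @return path to the manifest CSV, invisibly; the manifest has columns
#'   marker_path, dapi_path, line, passage, marker, bio_rep, tech_rep,
#'   is_control.
#' @export
simulate_image_set <- function(out_dir, base_params = image_sim_params(),
                               lines = "NSC-SIM", passages = c(5L, 25L),
                               markers = "GFAP", n_bio = 2L, n_tech = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); k <- 0L; field <- 0L
  for (line in lines) for (pg in passages) for (mk in markers)
    for (b in seq_len(n_bio)) for (t in seq_len(n_tech))
      for (ctl in c(FALSE, TRUE)) {
        field <- field + 1L
        p <- base_params
        p$seed <- child_seed(base_params$seed, field)
        pair <- simulate_image_pair(p, control = ctl,
                                    meta = list(line = line, passage = pg,
                                                marker_name = mk,
                                                bio_rep = b, tech_rep = t))
        stem <- sprintf("%s_p%d_%s_b%d_t%d_%s", line, pg, mk, b, t,
                        if (ctl) "control" else "stained")
        mk_path <- file.path(out_dir, paste0(stem, "_marker.tif"))
        da_path <- file.path(out_dir, paste0(stem, "_dapi.tif"))
        write_gray_tiff(pair$marker$pixels, mk_path, p$bit_depth)
        write_gray_tiff(pair$nuclei$pixels, da_path, p$bit_depth)
        k <- k + 1L
        rows[[k]] <- data.frame(marker_path = mk_path, dapi_path = da_path,
                                line = line, passage = pg, marker = mk,
                                bio_rep = b, tech_rep = t, is_control = ctl,
                                stringsAsFactors = FALSE)
      }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
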