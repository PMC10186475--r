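# Relative qPCR expression by the minus-delta-delta-Ct method and
# geNorm-style reference-gene stability ranking.
#
# Conventions: amplification efficiency 2.00 per cycle (one cycle = one
# doubling; no standard-curve correction). Multi-reference normalization
# uses the arithmetic mean of reference Ct values, equivalent to the
# geometric mean of the linear relative quantities 2^(-Ct) — the geNorm
# normalization-factor convention. Technical replicates are averaged before
# biological-replicate statistics; the technical-replicate dispersion is
# retained because figures conventionally show it as error bars.

#' Build a Ct table from a long-format data.frame
#'
#' @param df data.frame with columns gene, sample, group, bio_rep, tech_rep,
#'   ct (finite, > 0 cycles).
#' @param reference_genes declared reference (housekeeping) gene ids; must
#'   be measured in every sample.
#' @return the validated data.frame, class `ct_table`, with attribute
#'   `reference_genes`.
#' @export
ct_table <- function(df, reference_genes = character(0)) {
  need <- c("gene", "sample", "group", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ct table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and > 0")
  for (r in reference_genes) for (s in unique(df$sample))
    if (!any(df$gene == r & df$sample == s))
      stop("reference gene ", r, " missing in sample ", s)
  attr(df, "reference_genes") <- reference_genes
  class(df) <- c("ct_table", "data.frame")
  df
}

# One Ct per (gene, sample): mean over technical replicates, with their sd
# and count retained.
collapse_technical <- function(table) {
  agg <- aggregate(ct ~ gene + sample + group + bio_rep, data = table,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- agg[, c("gene", "sample", "group", "bio_rep")]
  out$ct <- agg$ct[, "mean"]
  out$ct_sd_tech <- agg$ct[, "sd"]
  out$n_tech <- agg$ct[, "n"]
  out
}

#' geNorm-style reference-gene stability ranking
#'
#' For each candidate j, the stability measure M_j is the mean, over the
#' other candidates k, of the standard deviation across samples of the
#' per-sample log2 expression ratio of j versus k. With relative quantities
#' Q = 2^(-Ct), that log ratio is `Ct_k - Ct_j`, so M is computed directly
#' on technically-averaged Ct values. Lower M means more stable; perfectly
#' co-varying candidates have M = 0. The iterative gene-elimination and
#' V(n/n+1) pairwise-variation cutoff of the full geNorm procedure are out
#' of scope: this is the ranking step used to choose references.
#'
#' @param table a [ct_table()] (or compatible data.frame).
#' @param candidates character vector (>= 2) of candidate reference genes,
#'   each measured in every sample.
#' @return data.frame (gene, M) sorted ascending by M, class
#'   `stability_ranking`.
#' @export
reference_stability <- function(table, candidates) {
  if (length(candidates) < 2) stop("need at least two candidate genes")
  flat <- collapse_technical(table)
  samples <- sort(unique(flat$sample))
  ctm <- matrix(NA_real_, length(candidates), length(samples),
                dimnames = list(candidates, samples))
  for (g in candidates) {
    sub <- flat[flat$gene == g, ]
    missing <- setdiff(samples, sub$sample)
    if (length(missing))
      stop("candidate ", g, " missing in sample(s): ",
           paste(missing, collapse = ", "))
    ctm[g, sub$sample] <- sub$ct
  }
  M <- vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) sd(ctm[k, ] - ctm[j, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = candidates, M = unname(M), stringsAsFactors = FALSE)
  out <- out[order(out$M, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Relative expression by the minus-delta-delta-Ct method
#'
#' Technical replicates are averaged to one Ct per (gene, biological
#' sample). Per sample, `dCt = Ct_target - mean(Ct_references)`; per group,
#' `ddCt = mean dCt(group) - mean dCt(calibrator)`. The statistic reported
#' is `-ddCt` (log2 fold-change scale) and the fold change `2^(-ddCt)`.
#' The calibrator group has `-ddCt = 0` by construction. Dispersions over
#' technical replicates (error-bar convention) and over biological samples
#' are both reported.
#'
#' @param table a [ct_table()] or compatible data.frame.
#' @param references reference gene ids; a single reference is allowed with
#'   a warning.
#' @param calibrator calibrator group label (defaults to the table's first
#'   group).
#' @return list of class `relative_expression`: `summary` (gene, group,
#'   minus_ddct, fold_change, sd_tech, sd_bio, n), and `per_sample` (the
#'   per-sample dCt and -ddCt values used, the unit for group tests).
#' @export
delta_delta_ct <- function(table, references = attr(table, "reference_genes"),
                           calibrator = NULL) {
  if (is.null(references) || length(references) == 0)
    stop("no reference genes given")
  if (length(references) == 1)
    warning("single reference gene: normalization has no stability safeguard")
  groups <- unique(table$group)
  if (is.null(calibrator)) calibrator <- groups[1]
  if (!calibrator %in% groups) stop("calibrator group not present: ", calibrator)
  flat <- collapse_technical(table)
  targets <- setdiff(unique(flat$gene), references)
  ref_by_sample <- tapply(flat$ct[flat$gene %in% references],
                          flat$sample[flat$gene %in% references], mean)
  # technical-replicate sd of dCt, propagated from target and reference reps
  raw <- table
  per_sample <- do.call(rbind, lapply(targets, function(g) {
    sub <- flat[flat$gene == g, ]
    if (!any(sub$group == calibrator))
      stop("target gene ", g, " absent in calibrator group ", calibrator)
    sub$dct <- sub$ct - as.numeric(ref_by_sample[sub$sample])
    sub$gene <- g
    sub
  }))
  out_rows <- list(); ps_rows <- list(); k <- 0L
  for (g in targets) {
    sub <- per_sample[per_sample$gene == g, ]
    cal <- mean(sub$dct[sub$group == calibrator])
    sub$minus_ddct <- -(sub$dct - cal)
    ps_rows[[g]] <- sub
    for (gr in groups) {
      gsub <- sub[sub$group == gr, ]
      ddct <- mean(gsub$dct) - cal
      # technical dispersion: sd over the raw technical-replicate dCt values
      raw_g <- raw[raw$gene == g & raw$group == gr, ]
      raw_dct <- raw_g$ct - as.numeric(ref_by_sample[raw_g$sample])
      k <- k + 1L
      out_rows[[k]] <- data.frame(gene = g, group = gr,
                                  minus_ddct = -ddct,
                                  fold_change = 2^(-ddct),
                                  sd_tech = sd(raw_dct),
                                  sd_bio = sd(gsub$dct),
                                  n = nrow(gsub), stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, c(out_rows, list(make.row.names = FALSE))),
                 per_sample = do.call(rbind, c(ps_rows, list(make.row.names = FALSE))),
                 references = references, calibrator = calibrator),
            class = "relative_expression")
}

#' Welch comparison of relative expression between two groups
#'
#' Two-sided Welch t-test on the per-biological-sample `-ddCt` values of one
#' target gene, with significance stars at 0.05 / 0.01 / 0.001. No
#' multiple-testing correction is applied across genes (per-gene stars, a
#' documented limitation).
#'
#' @param expr a [delta_delta_ct()] result.
#' @param gene target gene id.
#' @param groups length-2 character vector of group labels.
#' @return a `group_comparison`.
#' @export
welch_compare <- function(expr, gene, groups) {
  stopifnot(inherits(expr, "relative_expression"), length(groups) == 2)
  ps <- expr$per_sample
  x <- ps$minus_ddct[ps$gene == gene & ps$group == groups[1]]
  y <- ps$minus_ddct[ps$gene == gene & ps$group == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    cmp <- welch_comparison(x, y, labels = groups)
    return(cmp)  # computable = FALSE marker, difference still reported
  }
  welch_comparison(x, y, labels = groups)
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("Relative expression (-ddCt), references: %s; calibrator: %s\n",
              paste(x$references, collapse = "+"), x$calibrator))
  print(x$summary)
  invisible(x)
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("geNorm-style stability ranking (lower M = more stable)\n")
  print.data.frame(x)
  invisible(x)
}

#' Read a long-format Ct CSV
#'
#' @param path CSV with columns gene, sample, group, bio_rep, tech_rep, ct.
#' @param reference_genes declared reference gene ids.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path, reference_genes = character(0)) {
  ct_table(read.csv(path, stringsAsFactors = FALSE), reference_genes)
}
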