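# Integral squared-brightness quantification of immunofluorescence images.
#
# The core statistic is a histogram-weighted index per channel,
#   index = sum over brightness levels b of  count(b) * b^2,
# identically equal to the per-pixel sum of squared intensities. Squaring
# up-weights bright (stained) structures relative to dim background. The
# marker-channel index is normalized by the DAPI nuclei-channel index of the
# same field, giving a per-field fluorescence ratio that is then compared
# across conditions and against secondary-only negative controls.

#' Construct a fluorescence image object
#'
#' Wraps a nonnegative integer intensity matrix with its bit depth and
#' channel role. All quantification functions operate on raw stored
#' intensities: no rescaling to `[0, 1]` is applied, so both channels of a
#' pair must share a bit depth for the ratio to be scale-consistent.
#'
#' @param pixels nonnegative integer matrix of intensities.
#' @param bit_depth 8 or 16; all values must lie in `[0, 2^bit_depth - 1]`.
#' @param channel_role `"marker"` or `"nuclei"`.
#' @return an object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, bit_depth = 16L, channel_role = c("marker", "nuclei")) {
  channel_role <- match.arg(channel_role)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.matrix(pixels) || length(pixels) == 0) stop("pixels must be a non-empty matrix")
  if (is.array(pixels) && length(dim(pixels)) > 2)
    stop("color images are refused: extract a named channel explicitly")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 2^bit_depth - 1))
    stop("pixel values must be integers in [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = bit_depth, channel_role = channel_role),
            class = "fluor_image")
}

#' Construct an image pair (marker + nuclei channel of one field)
#'
#' @param marker,nuclei `fluor_image` objects of identical dimensions and
#'   bit depth; roles are reassigned to marker/nuclei respectively.
#' @param line,passage,marker_name,bio_rep,tech_rep metadata carried through
#'   to results tables.
#' @param is_control `TRUE` for a secondary-antibody-only negative control.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(marker, nuclei, line = NA_character_, passage = NA_integer_,
                       marker_name = NA_character_, bio_rep = NA_integer_,
                       tech_rep = NA_integer_, is_control = FALSE) {
  stopifnot(inherits(marker, "fluor_image"), inherits(nuclei, "fluor_image"))
  if (!identical(dim(marker$pixels), dim(nuclei$pixels)))
    stop("marker and nuclei images must have identical dimensions")
  if (marker$bit_depth != nuclei$bit_depth)
    stop("marker and nuclei images must share a bit depth")
  marker$channel_role <- "marker"; nuclei$channel_role <- "nuclei"
  structure(list(marker = marker, nuclei = nuclei,
                 meta = list(line = line, passage = passage,
                             marker_name = marker_name, bio_rep = bio_rep,
                             tech_rep = tech_rep,
                             is_control = isTRUE(is_control))),
            class = "image_pair")
}

#' Integral squared-brightness index of one channel
#'
#' Computes the channel index as the sum over histogram bins (one bin per
#' integer intensity level) of bin count times brightness squared. This
#' equals the per-pixel sum of squared intensities exactly; the histogram
#' route is used so the result is a pure function of the image histogram.
#'
#' @param image a `fluor_image`, or an integer matrix (then `bit_depth`
#'   applies).
#' @param bit_depth used only when `image` is a bare matrix.
#' @return list of class `channel_index` with `value` (sum of squared
#'   brightness), `n_pixels`, and `saturation_fraction` (fraction of pixels
#'   at the maximum representable value; above 0.01 a quality warning is
#'   attached as attribute `saturated`).
#' @examples
#' channel_index(matrix(3L, 2, 2), bit_depth = 8)$value  # 4 * 3^2 = 36
#' @export
channel_index <- function(image, bit_depth = 16L) {
  if (!inherits(image, "fluor_image")) image <- fluor_image(image, bit_depth)
  px <- image$pixels
  n_levels <- 2L^image$bit_depth
  counts <- tabulate(as.vector(px) + 1L, nbins = n_levels)
  brightness <- as.numeric(seq_len(n_levels) - 1L)
  value <- sum(counts * brightness^2)   # doubles are exact here (< 2^53)
  sat <- counts[n_levels] / length(px)
  out <- structure(list(value = value, n_pixels = length(px),
                        saturation_fraction = sat),
                   class = "channel_index")
  attr(out, "saturated") <- sat > 0.01
  out
}

#' Marker/DAPI fluorescence ratio of an image pair
#'
#' The ratio of the marker-channel index to the nuclei-channel index. It
#' represents the level of antibody fluorescence per amount of nuclear
#' (DAPI) signal in the field and is the unit of all downstream group
#' statistics.
#'
#' @param pair an `image_pair`.
#' @return list of class `fluorescence_ratio` with `value`, both channel
#'   indices, and the pair metadata.
#' @export
fluorescence_ratio <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  mi <- channel_index(pair$marker)
  ni <- channel_index(pair$nuclei)
  if (ni$value <= 0)
    stop("undefined ratio: nuclei-channel index is zero (field has no cells)")
  structure(list(value = mi$value / ni$value,
                 marker_index = mi, nuclei_index = ni, meta = pair$meta),
            class = "fluorescence_ratio")
}

#' Quantify a batch of image pairs
#'
#' Computes the fluorescence ratio for every pair and returns a tidy table,
#' one row per input pair in input order. Pairs whose ratio cannot be
#' computed (mismatched channels, empty nuclei channel) are flagged in the
#' `error` column, never dropped.
#'
#' @param pairs list of `image_pair` objects, or a manifest `data.frame` as
#'   read by [read_manifest()] (paths are then loaded from disk).
#' @return data.frame with metadata columns, `marker_index`, `nuclei_index`,
#'   `ratio`, `saturation_marker`, `saturation_nuclei`, `ok`, `error`.
#' @export
batch_quantify <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- load_manifest_pairs(pairs)
  if (length(pairs) == 0)
    return(data.frame(pair = integer(0), line = character(0),
                      passage = integer(0), marker = character(0),
                      bio_rep = integer(0), tech_rep = integer(0),
                      is_control = logical(0), marker_index = numeric(0),
                      nuclei_index = numeric(0), ratio = numeric(0),
                      saturation_marker = numeric(0),
                      saturation_nuclei = numeric(0), ok = logical(0),
                      error = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    meta <- if (inherits(p, "image_pair")) {
      p$meta
    } else if (inherits(p, "image_pair_error")) {
      list(line = p$meta$line, passage = p$meta$passage,
           marker_name = p$meta$marker, bio_rep = p$meta$bio_rep,
           tech_rep = p$meta$tech_rep, is_control = p$meta$is_control)
    } else {
      list(line = NA, passage = NA, marker_name = NA, bio_rep = NA,
           tech_rep = NA, is_control = NA)
    }
    base <- data.frame(pair = i,
                       line = as.character(meta$line),
                       passage = as.integer(meta$passage),
                       marker = as.character(meta$marker_name),
                       bio_rep = as.integer(meta$bio_rep),
                       tech_rep = as.integer(meta$tech_rep),
                       is_control = as.logical(meta$is_control),
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      if (inherits(p, "image_pair_error")) stop(p$message)
      if (!inherits(p, "image_pair")) stop("not an image pair")
      r <- fluorescence_ratio(p)
      cbind(base,
            marker_index = r$marker_index$value,
            nuclei_index = r$nuclei_index$value,
            ratio = r$value,
            saturation_marker = r$marker_index$saturation_fraction,
            saturation_nuclei = r$nuclei_index$saturation_fraction,
            ok = TRUE, error = NA_character_)
    }, error = function(e) {
      cbind(base, marker_index = NA_real_, nuclei_index = NA_real_,
            ratio = NA_real_, saturation_marker = NA_real_,
            saturation_nuclei = NA_real_, ok = FALSE,
            error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Welch unequal-variance t-test wrapped into the GroupComparison record.
# Degenerate inputs (both groups constant and equal) use the p = 1
# convention rather than erroring; real micrograph batches can contain
# identical blank fields.
welch_comparison <- function(x, y, labels = c("group1", "group2"),
                             alternative = "two.sided") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  out <- list(group1 = labels[1], group2 = labels[2],
              mean1 = mean(x), mean2 = mean(y),
              sd1 = sd(x), sd2 = sd(y),
              n1 = length(x), n2 = length(y),
              difference = mean(x) - mean(y),
              statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              stars = "", computable = FALSE, alternative = alternative)
  if (length(x) >= 2 && length(y) >= 2) {
    tt <- tryCatch(t.test(x, y, alternative = alternative, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {  # both essentially constant
      equal <- isTRUE(all.equal(mean(x), mean(y)))
      out$statistic <- if (equal) 0 else sign(out$difference) * Inf
      out$df <- length(x) + length(y) - 2
      out$p_value <- if (equal) 1 else 0
    } else {
      out$statistic <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_value <- unname(tt$p.value)
    }
    out$stars <- significance_stars(out$p_value)
    out$computable <- TRUE
  }
  structure(out, class = "group_comparison")
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p a p-value (vectorized).
#' @return `""`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Compare stained fields against negative controls
#'
#' A marker is called *detected* when stained fluorescence ratios exceed the
#' matched secondary-only controls: the one-sided Welch test of
#' stained > control, at p < 0.05, with a positive mean difference. With
#' fewer than two observations on either side only the difference is
#' reported and the test is marked not computable.
#'
#' @param stained,controls numeric vectors of fluorescence ratios.
#' @return a `group_comparison` with an added `detected` flag.
#' @export
control_comparison <- function(stained, controls) {
  if (length(stained) < 1 || length(controls) < 1)
    stop("need at least one ratio per side")
  cmp <- welch_comparison(stained, controls, labels = c("stained", "control"),
                          alternative = "greater")
  cmp$detected <- isTRUE(cmp$computable && cmp$difference > 0 && cmp$p_value < 0.05)
  cmp
}

#' Two-sided Welch comparison of fluorescence ratios between two conditions
#'
#' Used for passage or line contrasts (e.g. passage 5 vs passage 25 of one
#' marker). Technical replicates should be averaged within biological
#' replicate first ([average_technical_replicates()]) to avoid
#' pseudo-replication.
#'
#' @param x,y numeric vectors of ratios for the two conditions.
#' @param labels length-2 character vector naming the groups.
#' @return a `group_comparison`: means, sds, ns, Welch t, Welch-Satterthwaite
#'   df, two-sided p, significance stars.
#' @export
group_compare <- function(x, y, labels = c("group1", "group2")) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs n >= 2 for a Welch comparison")
  welch_comparison(x, y, labels = labels, alternative = "two.sided")
}

#' Average technical replicates within biological replicate
#'
#' Collapses a [batch_quantify()] results table to one ratio per
#' (line, passage, marker, is_control, biological replicate), the unit on
#' which group tests are run. Rows with failed ratios are excluded.
#'
#' @param results data.frame from [batch_quantify()].
#' @return data.frame with one averaged `ratio` per biological replicate.
#' @export
average_technical_replicates <- function(results) {
  ok <- results[!is.na(results$ratio), , drop = FALSE]
  if (nrow(ok) == 0) return(ok[, c("line", "passage", "marker", "is_control", "bio_rep", "ratio")])
  aggregate(ratio ~ line + passage + marker + is_control + bio_rep,
            data = ok, FUN = mean)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch comparison (%s): %s vs %s\n", x$alternative, x$group1, x$group2))
  cat(sprintf("  mean %s = %.4g (sd %.3g, n %d); mean %s = %.4g (sd %.3g, n %d)\n",
              x$group1, x$mean1, x$sd1, x$n1, x$group2, x$mean2, x$sd2, x$n2))
  if (x$computable)
    cat(sprintf("  difference = %.4g, t = %.3f, df = %.2f, p = %.4g %s\n",
                x$difference, x$statistic, x$df, x$p_value, x$stars))
  else
    cat(sprintf("  difference = %.4g (test not computable: n < 2 in a group)\n",
                x$difference))
  invisible(x)
}

#' @export
print.channel_index <- function(x, ...) {
  cat(sprintf("channel index: %.6g over %d pixels (saturation %.3g)\n",
              x$value, x$n_pixels, x$saturation_fraction))
  invisible(x)
}

#' @export
print.fluorescence_ratio <- function(x, ...) {
  cat(sprintf("fluorescence ratio (marker/DAPI): %.6g\n", x$value))
  invisible(x)
}
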