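# Manifest-driven image I/O.

MANIFEST_COLS <- c("marker_path", "dapi_path", "line", "passage", "marker",
                   "bio_rep", "tech_rep", "is_control")

#' Read an image-pair manifest CSV
#'
#' @param path CSV with columns marker_path, dapi_path, line, passage,
#'   marker, bio_rep, tech_rep, is_control. Relative image paths are
#'   resolved against the manifest's directory.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLS, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  root <- dirname(normalizePath(path))
  fix <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  df$marker_path <- fix(df$marker_path)
  df$dapi_path <- fix(df$dapi_path)
  df$is_control <- as.logical(df$is_control)
  df
}

# Load the image pairs a manifest row describes; per-row failures surface
# later as flagged rows in batch_quantify, so errors here become error
# placeholders rather than aborting the batch.
load_manifest_pairs <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tryCatch({
      mk <- read_gray_tiff(row$marker_path)
      da <- read_gray_tiff(row$dapi_path)
      image_pair(fluor_image(mk, attr(mk, "bit_depth"), "marker"),
                 fluor_image(da, attr(da, "bit_depth"), "nuclei"),
                 line = row$line, passage = row$passage,
                 marker_name = row$marker, bio_rep = row$bio_rep,
                 tech_rep = row$tech_rep, is_control = row$is_control)
    }, error = function(e) structure(list(message = conditionMessage(e),
                                          meta = as.list(row)),
                                     class = "image_pair_error"))
  })
}
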