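#' Preprocessing configuration for MPM planes
#'
#' @param bin_factor integer >= 1; block size for mean-binning.
#' @param normalization `"minmax"`, `"zscore"` or `"none"`.
#' @param auto_threshold `"otsu"` for automated Otsu thresholding or
#'   `"fixed"` for a user-supplied (manual) threshold.
#' @param fixed_threshold numeric threshold, required iff
#'   `auto_threshold = "fixed"`.
#' @param morph_open_radius_px radius (pixels) of the morphological opening
#'   applied to masks; 0 disables opening.
#' @return list of class `preprocess_config`.
#' @examples
#' preprocess_config(bin_factor = 2)
#' @export
preprocess_config <- function(bin_factor = 1L, normalization = "minmax",
                              auto_threshold = "otsu",
                              fixed_threshold = NULL,
                              morph_open_radius_px = 1L) {
  normalization <- match.arg(normalization, c("minmax", "zscore", "none"))
  auto_threshold <- match.arg(auto_threshold, c("otsu", "fixed"))
  if (bin_factor < 1L) stop("'bin_factor' must be >= 1")
  if (auto_threshold == "fixed" && is.null(fixed_threshold))
    stop("'fixed_threshold' is required when auto_threshold = 'fixed'")
  if (auto_threshold == "otsu" && !is.null(fixed_threshold))
    stop("'fixed_threshold' is only meaningful with auto_threshold = 'fixed'")
  structure(list(bin_factor = as.integer(bin_factor),
                 normalization = normalization,
                 auto_threshold = auto_threshold,
                 fixed_threshold = fixed_threshold,
                 morph_open_radius_px = as.integer(morph_open_radius_px)),
            class = "preprocess_config")
}

#' Mean-bin an image by an integer factor
#'
#' Each output pixel is the mean of its `factor` x `factor` input block.
#' If `factor` does not divide a dimension, the image is cropped to the
#' largest divisible region first.
#'
#' @param img numeric matrix.
#' @param factor integer >= 1.
#' @return matrix of shape `floor(dim(img) / factor)`.
#' @examples
#' bin_image(matrix(c(1, 5, 3, 7), 2, 2), 2)  # mean of all four = 4
#' @export
bin_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be >= 1")
  if (factor == 1L) return(img)
  H <- (nrow(img) %/% factor) * factor
  W <- (ncol(img) %/% factor) * factor
  if (H < factor || W < factor) stop("image smaller than one bin")
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  # fold rows then columns
  r <- matrix(colMeans(matrix(img, nrow = factor)), nrow = H %/% factor)
  t(matrix(colMeans(matrix(t(r), nrow = factor)), nrow = W %/% factor))
}

#' Normalize an image channel
#'
#' `"minmax"` maps the in-plane minimum to 0 and maximum to 1 (a constant
#' image maps to all zeros); `"zscore"` maps to mean 0, sd 1; `"none"`
#' returns the input.
#'
#' @param img numeric matrix with finite entries.
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @return normalized matrix.
#' @export
normalize_channel <- function(img, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  if (!all(is.finite(img))) stop("image must be finite")
  switch(method,
         none = img,
         minmax = {
           r <- range(img)
           if (diff(r) == 0) return(img * 0)
           (img - r[1]) / diff(r)
         },
         zscore = {
           s <- sd(img)
           if (s == 0) return(img * 0)
           (img - mean(img)) / s
         })
}

new_roi_mask <- function(mask, source) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, source = source), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %dx%d  source=%s  foreground=%d px>\n",
              nrow(x$mask), ncol(x$mask), x$source, sum(x$mask)))
  invisible(x)
}

#' Automated (or fixed-threshold) foreground mask
#'
#' Thresholds a normalized channel with Otsu's method (automated path) or
#' a user-supplied fixed threshold (the "manual" path), then removes
#' speckle with a morphological opening of the configured radius.
#'
#' @param img normalized numeric matrix.
#' @param cfg a [preprocess_config()].
#' @param source mask provenance tag (`"shg_auto"`, `"tpef_auto"`,
#'   `"manual"`).
#' @return `roi_mask` object. Errors if the resulting mask is empty.
#' @export
auto_mask <- function(img, cfg = preprocess_config(), source = "shg_auto") {
  thr <- if (cfg$auto_threshold == "fixed") cfg$fixed_threshold else {
    r <- range(img)
    if (diff(r) == 0) stop("empty mask: constant image has no foreground")
    EBImage::otsu(EBImage::Image((img - r[1]) / diff(r)),
                  range = c(0, 1), levels = 256L) * diff(r) + r[1]
  }
  m <- img > thr
  if (cfg$morph_open_radius_px > 0L && any(m)) {
    brush <- EBImage::makeBrush(2L * cfg$morph_open_radius_px + 1L, "disc")
    m <- EBImage::opening(m, brush) > 0
  }
  if (!any(m)) stop("empty mask: no foreground after thresholding/opening")
  new_roi_mask(m, if (cfg$auto_threshold == "fixed") "manual" else source)
}

#' Combine two masks with a logical OR
#'
#' The training masks for radiomics are the union of the per-channel SHG
#' and TPEF masks, so that collagen-only and myocyte-only regions both
#' enter feature extraction.
#'
#' @param m1,m2 `roi_mask` objects of identical shape.
#' @return `roi_mask` with `source = "or_combined"`.
#' @export
combine_masks_or <- function(m1, m2) {
  stopifnot(inherits(m1, "roi_mask"), inherits(m2, "roi_mask"))
  if (!identical(dim(m1$mask), dim(m2$mask)))
    stop("mask shape mismatch")
  new_roi_mask(m1$mask | m2$mask, "or_combined")
}

#' Preprocess one MPM plane
#'
#' Applies binning and per-channel normalization, builds the per-channel
#' automated masks and their OR combination.
#'
#' @param plane an `mpm_plane`.
#' @param cfg a [preprocess_config()].
#' @return list with `shg`, `tpef` (processed channels), `mask_shg`,
#'   `mask_tpef`, `mask` (OR-combined `roi_mask`), and the input metadata.
#' @export
preprocess_plane <- function(plane, cfg = preprocess_config()) {
  stopifnot(inherits(plane, "mpm_plane"))
  shg <- normalize_channel(bin_image(plane$shg, cfg$bin_factor),
                           cfg$normalization)
  tpef <- normalize_channel(bin_image(plane$tpef, cfg$bin_factor),
                            cfg$normalization)
  m1 <- auto_mask(shg, cfg, "shg_auto")
  m2 <- auto_mask(tpef, cfg, "tpef_auto")
  list(shg = shg, tpef = tpef, mask_shg = m1, mask_tpef = m2,
       mask = combine_masks_or(m1, m2), tissue_class = plane$tissue_class,
       binary_label = plane$binary_label, roi_id = plane$roi_id,
       depth_index = plane$depth_index)
}
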