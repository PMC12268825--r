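#' Fixed-bin-number discretization of a masked image
#'
#' Maps in-mask intensities onto integer gray levels `1..n_levels` with the
#' fixed bin number rule
#' `level = min(N_g, floor(N_g * (x - min) / (max - min)) + 1)`,
#' computed over in-mask pixels only. A constant in-mask region maps to
#' level 1. Out-of-mask pixels are coded 0.
#'
#' @param img numeric matrix.
#' @param mask `roi_mask` or logical matrix of the same shape.
#' @param n_levels number of gray levels (>= 2).
#' @return list of class `discretized_image` with `levels` (integer
#'   matrix, 0 outside the mask), `n_levels`, `mask` (logical matrix).
#' @examples
#' d <- discretize(matrix(c(0, .5, 1, 0), 2), matrix(TRUE, 2, 2), 2)
#' d$levels
#' @export
discretize <- function(img, mask, n_levels = 32L) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) stop("empty mask")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  x <- img[mask]
  r <- range(x)
  lev <- matrix(0L, nrow(img), ncol(img))
  if (diff(r) == 0) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(n_levels,
                      as.integer(floor(n_levels * (x - r[1]) / diff(r))) + 1L)
  }
  structure(list(levels = lev, n_levels = n_levels, mask = mask),
            class = "discretized_image")
}
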