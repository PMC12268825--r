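#' 2D morphology features of a mask (14 features)
#'
#' Shape descriptors of the ROI mask: pixel area, boundary perimeter
#' (count of pixel edges between mask and background, including the image
#' border), perimeter-to-area ratio, circularity `4*pi*A/P^2`, compactness
#' `P^2/A`, equivalent disc diameter, major/minor axis lengths from the
#' central second moments, eccentricity, elongation (minor/major),
#' extent (area / bounding-box area), solidity (area / convex hull area),
#' centre-of-mass shift (distance between the mask centroid and the
#' intensity-weighted centroid), and the number of 8-connected components.
#'
#' All descriptors are invariant under 90-degree rotations of the plane.
#'
#' @param img numeric matrix (used for the centre-of-mass shift only).
#' @param mask `roi_mask` or logical matrix.
#' @return named numeric vector of 14 features.
#' @export
morphology_features <- function(img, mask) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  H <- nrow(mask); W <- ncol(mask)
  A <- sum(mask)
  # perimeter: mask/background edges, image border counts as background
  pm <- matrix(FALSE, H + 2L, W + 2L)
  pm[2:(H + 1L), 2:(W + 1L)] <- mask
  per <- sum(pm[2:(H + 1L), 2:(W + 1L)] & !pm[1:H, 2:(W + 1L)]) +
         sum(pm[2:(H + 1L), 2:(W + 1L)] & !pm[3:(H + 2L), 2:(W + 1L)]) +
         sum(pm[2:(H + 1L), 2:(W + 1L)] & !pm[2:(H + 1L), 1:W]) +
         sum(pm[2:(H + 1L), 2:(W + 1L)] & !pm[2:(H + 1L), 3:(W + 2L)])
  rr <- .row(dim(mask))[mask]; cc <- .col(dim(mask))[mask]
  cy <- mean(rr); cx <- mean(cc)
  # central second moments
  myy <- mean((rr - cy)^2); mxx <- mean((cc - cx)^2)
  mxy <- mean((rr - cy) * (cc - cx))
  tr <- mxx + myy
  det_ <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
  l1 <- (tr + det_) / 2; l2 <- (tr - det_) / 2
  major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  elong <- if (major > 0) minor / major else 1
  bbox <- (diff(range(rr)) + 1) * (diff(range(cc)) + 1)
  hull_area <- convex_hull_area(rr, cc)
  w <- img[mask]
  sw <- sum(w)
  com <- if (sw > 0)
    sqrt((sum(w * rr) / sw - cy)^2 + (sum(w * cc) / sw - cx)^2) else 0
  ncomp <- max(label_zones8(mask), 1L)
  c(area = A,
    perimeter = per,
    pa.ratio = per / A,
    circularity = 4 * pi * A / per^2,
    compactness = per^2 / A,
    equiv.diam = 2 * sqrt(A / pi),
    major.axis = major,
    minor.axis = minor,
    eccentricity = ecc,
    elongation = elong,
    extent = A / bbox,
    solidity = A / max(hull_area, A),
    com.shift = com,
    n.components = ncomp)
}

# Area of the convex hull of pixel centres (shoelace over chull order);
# degenerate (collinear) masks fall back to the pixel count.
convex_hull_area <- function(rr, cc) {
  pts <- unique(cbind(cc, rr))
  if (nrow(pts) < 3L) return(length(rr))
  h <- chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  max(area, length(rr))
}
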