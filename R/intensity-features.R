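# Intensity-based statistics, intensity histogram features (on the
# discretized levels), and local intensity peaks.

#' Intensity range within the mask
#'
#' @param img numeric matrix.
#' @param mask `roi_mask` or logical matrix.
#' @return max - min of in-mask intensities.
#' @export
feature_intensity_range <- function(img, mask) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  diff(range(img[mask]))
}

# disc-neighborhood mean around every pixel, mask-respecting:
# conv(img * mask) / conv(mask) with a Euclidean-disc kernel.
disc_means <- function(img, mask, radius_px) {
  r <- ceiling(radius_px)
  g <- seq(-r, r)
  kern <- outer(g, g, function(a, b) as.numeric(a^2 + b^2 <= radius_px^2))
  num <- EBImage::filter2(img * mask, kern, boundary = 0)
  den <- EBImage::filter2(mask * 1.0, kern, boundary = 0)
  list(num = num, den = den)
}

#' Local intensity peak
#'
#' Mean intensity over in-mask pixels within `radius_px` (Euclidean) of
#' the maximum-intensity in-mask pixel; intensity ties are broken by the
#' smallest row-major index. `feature_global_intensity_peak()` is the
#' maximum of the same disc-mean over all in-mask pixels.
#'
#' @param img numeric matrix.
#' @param mask `roi_mask` or logical matrix.
#' @param radius_px disc radius in pixels (default 5).
#' @return mean intensity (scalar).
#' @export
feature_local_intensity_peak <- function(img, mask, radius_px = 5) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  vals <- ifelse(mask, img, -Inf)
  # row-major tie-break: scan transposed so earlier rows win first
  tv <- t(vals)
  k <- which.max(tv)  # first max in row-major order
  pr <- ((k - 1L) %/% ncol(img)) + 1L
  pc <- ((k - 1L) %% ncol(img)) + 1L
  rr <- .row(dim(img)); cc <- .col(dim(img))
  sel <- mask & ((rr - pr)^2 + (cc - pc)^2 <= radius_px^2)
  mean(img[sel])
}

#' @rdname feature_local_intensity_peak
#' @export
feature_global_intensity_peak <- function(img, mask, radius_px = 5) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  dm <- disc_means(img, mask, radius_px)
  means <- dm$num[mask] / dm$den[mask]
  max(means)
}

# both peak features from a single disc convolution (used by extract)
intensity_peaks <- function(img, mask, radius_px = 5) {
  if (!any(mask)) stop("empty mask")
  c(peak.local = feature_local_intensity_peak(img, mask, radius_px),
    peak.global = feature_global_intensity_peak(img, mask, radius_px))
}

#' Intensity-based statistics (18 features)
#'
#' Mean, variance, skewness, excess kurtosis, median, minimum, 10th/90th
#' percentiles, maximum, interquartile range, range, mean/robust-mean/
#' median absolute deviation, coefficient of variation, quartile
#' coefficient of dispersion, energy and root mean square of the in-mask
#' intensities (IBSI definitions; percentile type 7).
#'
#' @param img numeric matrix.
#' @param mask `roi_mask` or logical matrix.
#' @return named numeric vector of 18 features.
#' @export
intensity_statistics <- function(img, mask) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  x <- img[mask]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)       # population variance per IBSI
  s <- sqrt(v)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inr <- x[x >= q[1] & x <= q[5]]
  med <- q[3]
  c(mean = mu,
    var = v,
    skew = if (s > 0) mean((x - mu)^3) / s^3 else 0,
    kurt = if (s > 0) mean((x - mu)^4) / v^2 - 3 else 0,
    median = med,
    min = min(x),
    p10 = q[1],
    p90 = q[5],
    max = max(x),
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    madr = mean(abs(inr - mean(inr))),
    medad = mean(abs(x - med)),
    cov = if (mu != 0) s / mu else 0,
    qcod = if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    energy = sum(x^2),
    rms = sqrt(mean(x^2)))
}

#' Intensity histogram features (23 features)
#'
#' Statistics of the discretized gray levels plus histogram entropy,
#' uniformity and the maximum/minimum histogram gradients and their
#' locations (IBSI intensity-histogram family).
#'
#' @param d a [discretize()]d image.
#' @return named numeric vector of 23 features.
#' @export
intensity_histogram_features <- function(d) {
  stopifnot(inherits(d, "discretized_image"))
  x <- as.numeric(d$levels[d$mask])
  n <- length(x)
  Ng <- d$n_levels
  cnt <- tabulate(as.integer(x), nbins = Ng)
  p <- cnt / n
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inr <- x[x >= q[1] & x <= q[5]]
  med <- q[3]
  # histogram gradient over occupied level axis
  grad <- if (Ng >= 2) {
    gr <- numeric(Ng)
    gr[1] <- cnt[2] - cnt[1]
    gr[Ng] <- cnt[Ng] - cnt[Ng - 1]
    if (Ng > 2) gr[2:(Ng - 1)] <- (cnt[3:Ng] - cnt[1:(Ng - 2)]) / 2
    gr
  } else 0
  mode_lv <- which(cnt == max(cnt))[1]  # lowest level on ties
  c(mean = mu,
    var = v,
    skew = if (s > 0) mean((x - mu)^3) / s^3 else 0,
    kurt = if (s > 0) mean((x - mu)^4) / v^2 - 3 else 0,
    median = med,
    min = min(x),
    p10 = q[1],
    p90 = q[5],
    max = max(x),
    mode = mode_lv,
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    madr = mean(abs(inr - mean(inr))),
    medad = mean(abs(x - med)),
    cov = if (mu != 0) s / mu else 0,
    qcod = if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0,
    entropy = -sum(p[p > 0] * log2(p[p > 0])),
    uniformity = sum(p^2),
    max.grad = max(grad),
    max.grad.gl = which.max(grad),
    min.grad = min(grad),
    min.grad.gl = which.min(grad))
}
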