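# Minimum-redundancy maximum-relevance feature ranking.
#
# Mutual information is estimated on 4-quantile discretized features
# (deterministic and scale-free); the greedy criterion at each step is
# relevance minus mean redundancy with the already-selected set, ties
# broken by column order.

quantile_bin <- function(x, n_bins = 4L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))  # constant feature
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

mutual_information <- function(a, b) {
  # a, b: small positive integer codes
  na <- max(a); nb <- max(b)
  pj <- tabulate(a + na * (b - 1L), nbins = na * nb) / length(a)
  pa <- tabulate(a, nbins = na) / length(a)
  pb <- tabulate(b, nbins = nb) / length(b)
  pr <- as.vector(outer(pa, pb))
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / pr[nz]))
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking: the first feature
#' maximizes mutual information with the class label (relevance); each
#' subsequent feature maximizes relevance minus the mean mutual
#' information with the features already selected (redundancy). Features
#' are discretized into 4 quantile bins before estimating mutual
#' information, so the ranking is deterministic and scale-free. Ties are
#' broken by column order.
#'
#' @param x numeric matrix or data.frame of features (columns named).
#' @param labels class labels (two or more classes, factor or character).
#' @param d number of features to rank (default all).
#' @param n_bins quantile bins for discretization.
#' @return character vector of the `d` top-ranked feature names, in rank
#'   order.
#' @examples
#' x <- cbind(sig = rep(0:1, 10) + rnorm(20, 0, .01), noise = rnorm(20))
#' mrmr_rank(x, rep(c("a", "b"), 10))
#' @export
mrmr_rank <- function(x, labels, d = ncol(x), n_bins = 4L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2L) stop("labels must contain at least two classes")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  d <- min(d, ncol(x))
  if (d < 1L) stop("'d' must be >= 1")
  xb <- apply(x, 2, quantile_bin, n_bins = n_bins)
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(jj)
    mutual_information(xb[, jj], y), numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(d)) {
    score <- if (step == 1L) relevance[remaining] else
      relevance[remaining] - red_sum[remaining] / (step - 1L)
    pick <- remaining[which.max(score)]    # first max = column-order tie-break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) && step < d) {
      mi_new <- vapply(remaining, function(jj)
        mutual_information(xb[, jj], xb[, pick]), numeric(1))
      red_sum[remaining] <- red_sum[remaining] + mi_new
    }
  }
  colnames(x)[selected]
}
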