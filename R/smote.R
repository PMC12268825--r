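#' SMOTE oversampling of a minority class
#'
#' Generates synthetic minority samples by interpolation: each synthetic
#' row is `x + t * (x_nn - x)` with `t ~ Uniform(0, 1)` and `x_nn` one of
#' the `k_neighbors` nearest minority neighbors of the base row `x`
#' (Euclidean distance). Base rows are cycled in order so the synthetic
#' set spreads over the whole minority class.
#'
#' @param minority numeric matrix of minority-class rows (>= 2 rows).
#' @param k_neighbors number of nearest neighbors to draw from
#'   (`< nrow(minority)`).
#' @param n_synthetic number of synthetic rows to generate.
#' @param seed integer seed.
#' @return numeric matrix with `n_synthetic` rows; every row is a convex
#'   combination of two real minority rows.
#' @examples
#' smote_oversample(rbind(c(0, 0), c(2, 2)), 1, 3, seed = 1)
#' @export
smote_oversample <- function(minority, k_neighbors = 5L, n_synthetic,
                             seed = 1L) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (n < 2L) stop("minority class must have at least 2 rows")
  k_neighbors <- min(as.integer(k_neighbors), n - 1L)
  if (k_neighbors < 1L) stop("'k_neighbors' must be >= 1 and < minority size")
  if (n_synthetic < 1L) return(minority[0, , drop = FALSE])
  D <- as.matrix(stats::dist(minority))
  diag(D) <- Inf
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) nn[i, ] <- order(D[i, ])[seq_len(k_neighbors)]
  with_seed(seed, {
    base <- rep_len(seq_len(n), n_synthetic)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_synthetic,
                                      replace = TRUE))]
    t_ <- runif(n_synthetic)
    out <- minority[base, , drop = FALSE] +
      t_ * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
}

#' Balance a binary training set by SMOTE
#'
#' Oversamples the minority class until both classes have equal counts.
#'
#' @param x feature matrix.
#' @param y binary labels (factor or character).
#' @param k_neighbors SMOTE neighbor count.
#' @param seed integer seed.
#' @return list with balanced `x` and `y` (synthetic rows appended).
#' @export
smote_balance <- function(x, y, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2L) stop("smote_balance expects exactly two classes")
  mino <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  if (need == 0L) return(list(x = x, y = y))
  syn <- smote_oversample(x[y == mino, , drop = FALSE], k_neighbors, need,
                          seed = seed)
  list(x = rbind(x, syn), y = c(y, rep(mino, need)))
}
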