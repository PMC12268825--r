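#' Unique Monte-Carlo folds with minority-matched validation sets
#'
#' Builds `n_folds` random train/validation partitions of a binary
#' feature table. The validation set draws `v = round(fraction * minority
#' class size)` planes from each binary class (so validation is always
#' balanced); all remaining planes train. No two folds share the same
#' validation set.
#'
#' @param labels character/factor vector of binary labels
#'   (`"healthy"` / `"pathologic"`), or a `feature_table` whose
#'   `binary_label` column is used.
#' @param n_folds number of Monte-Carlo folds (default 20).
#' @param validation_fraction fraction of the minority class reserved for
#'   validation (default 0.2).
#' @param seed integer root seed; per-fold seeds are derived from it.
#' @return list of folds, each a list with `fold_id`, `validation`
#'   (row indices), `train` (row indices), `seed`.
#' @examples
#' f <- build_mc_folds(rep(c("healthy", "pathologic"), c(10, 20)),
#'                     n_folds = 3, seed = 1)
#' lengths(f[[1]])
#' @export
build_mc_folds <- function(labels, n_folds = 20L, validation_fraction = 0.2,
                           seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$binary_label
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("binary labels required")
  idx <- split(seq_along(y), y)
  sizes <- lengths(idx)
  mino <- min(sizes)
  if (mino < 5L) stop("minority class must have at least 5 samples")
  v <- max(1L, round(validation_fraction * mino))
  capacity <- choose(mino, v)  # distinct subsets of the smaller class
  if (n_folds > capacity)
    stop("requested n_folds exceeds the number of distinct validation sets")
  folds <- vector("list", n_folds)
  seen <- character(0)
  attempt <- 0L
  for (k in seq_len(n_folds)) {
    repeat {
      attempt <- attempt + 1L
      val <- with_seed(derive_seed(seed, 2L, attempt), {
        sort(c(sample(idx[[1]], v), sample(idx[[2]], v)))
      })
      key <- paste(val, collapse = ",")
      if (!key %in% seen) break
      if (attempt > 1000L * n_folds) stop("could not build unique folds")
    }
    seen <- c(seen, key)
    folds[[k]] <- list(fold_id = k, validation = val,
                       train = setdiff(seq_along(y), val),
                       seed = derive_seed(seed, 2L, attempt))
  }
  folds
}
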