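#' PLS-DA model (NIPALS PLS2 on one-hot class indicators)
#'
#' Fits partial least-squares discriminant analysis: the class membership
#' is coded as a one-hot indicator matrix Y, both X and Y are
#' mean-centered, and NIPALS extracts `k` latent variables (LVs) with
#' successive deflation of X and Y. The regression coefficient matrix
#' `B = W (P'W)^-1 Q'` maps centered spectra to class indicator
#' predictions. Each LV is sign-normalized so that the largest-magnitude
#' element of its X-loading is positive, making score and loading plots
#' reproducible across runs.
#'
#' @param set a preprocessed `raman_set`.
#' @param k number of latent variables (default 4, one per class;
#'   `k <= min(n - 1, channels)`).
#' @param tol NIPALS convergence tolerance.
#' @param max_iter NIPALS iteration cap per component.
#' @return list of class `pls_model`: `weights` (W), `loadings` (P),
#'   `y_loadings` (Q), `scores` (T), `B`, `x_center`, `y_center`,
#'   `classes`, `axis`, `k`, `x_var` (residual X variance per component).
#' @export
plsda_fit <- function(set, k = 4L, tol = 1e-24, max_iter = 1000L) {
  stopifnot(inherits(set, "raman_set"))
  labels <- droplevels(factor(set$labels))
  classes <- levels(labels)
  if (length(classes) < 2L) stop("at least two classes required")
  n <- nrow(set$X); p <- ncol(set$X)
  k <- as.integer(k)
  if (k > min(n - 1L, p)) stop("'k' too large for the data")
  Y <- outer(as.character(labels), classes, `==`) * 1.0
  colnames(Y) <- classes
  x_center <- colMeans(set$X)
  y_center <- colMeans(Y)
  X <- sweep(set$X, 2, x_center)
  Y <- sweep(Y, 2, y_center)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Q <- matrix(0, length(classes), k); Tm <- matrix(0, n, k)
  x_var <- numeric(k)
  for (a in seq_len(k)) {
    u <- Y[, which.max(apply(Y, 2, var))]
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      t_ <- X %*% w
      q <- crossprod(Y, t_) / sum(t_^2)
      u <- Y %*% q / sum(q^2)
      w_new <- crossprod(X, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sum((w_new - w)^2)
      w <- w_new
      if (delta < tol) break
    }
    t_ <- X %*% w
    q <- crossprod(Y, t_) / sum(t_^2)
    p_ <- crossprod(X, t_) / sum(t_^2)
    # sign convention: largest-|.| element of the X-loading is positive
    s <- sign(p_[which.max(abs(p_))])
    if (s < 0) { w <- -w; t_ <- -t_; p_ <- -p_; q <- -q }
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
    X <- X - t_ %*% t(p_)
    Y <- Y - t_ %*% t(q)
    x_var[a] <- sum(X^2)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(weights = W, loadings = P, y_loadings = Q, scores = Tm,
                 B = B, x_center = x_center, y_center = y_center,
                 classes = classes, axis = set$axis, k = k, x_var = x_var),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model  k=%d LVs  %d channels  classes: %s>\n",
              x$k, nrow(x$loadings), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Scores and loadings of one latent variable
#'
#' @param model a [plsda_fit()] model.
#' @param which `"LV1"` or `"LV2"` (or any `"LV<k>"` within the model).
#' @return list with `scores` (per training spectrum), `loadings` and
#'   `weights` (per wavenumber), `axis`, `labels` not included (keep the
#'   training set for that).
#' @export
plsda_scores_loadings <- function(model, which = "LV1") {
  stopifnot(inherits(model, "pls_model"))
  a <- as.integer(sub("^LV", "", which))
  if (is.na(a) || a < 1L) stop("'which' must be of the form 'LV<k>'")
  if (a > model$k)
    stop("component ", which, " not available: model has k = ", model$k)
  list(scores = model$scores[, a], loadings = model$loadings[, a],
       weights = model$weights[, a], axis = model$axis)
}

#' Predict classes for new spectra
#'
#' `yhat = (x - x_center) B + y_center`; the predicted class is the
#' argmax over class columns, ties resolved toward the first class in
#' canonical order.
#'
#' @param model a [plsda_fit()] model.
#' @param newdata a `raman_set` or spectra matrix with matching channel
#'   count (preprocessed identically to training).
#' @return factor of predicted classes.
#' @export
plsda_predict <- function(model, newdata) {
  X <- if (inherits(newdata, "raman_set")) newdata$X else as.matrix(newdata)
  if (ncol(X) != nrow(model$B))
    stop("channel-count mismatch with the trained model")
  Yhat <- sweep(X, 2, model$x_center) %*% model$B
  Yhat <- sweep(Yhat, 2, model$y_center, `+`)
  idx <- apply(Yhat, 1, which.max)  # which.max takes the first maximum
  factor(model$classes[idx], levels = model$classes)
}

#' Multiclass classification report
#'
#' 4x4 (or CxC) confusion matrix with per-class one-versus-rest
#' sensitivity and specificity, and their unweighted macro averages.
#'
#' @param predictions,truth aligned class labels.
#' @return list of class `multiclass_report`: `confusion` (rows = truth),
#'   `sensitivity`, `specificity` (per class), `overall_sensitivity`,
#'   `overall_specificity`.
#' @export
multiclass_metrics <- function(predictions, truth) {
  truth <- factor(as.character(truth))
  lev <- levels(truth)
  predictions <- as.character(predictions)
  if (!all(predictions %in% lev))
    stop("prediction contains class label unseen in truth: ",
         paste(setdiff(unique(predictions), lev), collapse = ", "))
  predictions <- factor(predictions, levels = lev)
  cm <- table(truth = truth, predicted = predictions)
  n <- sum(cm)
  sens <- diag(cm) / rowSums(cm)
  spec <- vapply(seq_along(lev), function(i) {
    fp <- sum(cm[-i, i]); tn <- n - sum(cm[i, ]) - fp
    tn / (tn + fp)
  }, numeric(1))
  names(spec) <- lev
  structure(list(confusion = cm, sensitivity = sens, specificity = spec,
                 overall_sensitivity = mean(sens),
                 overall_specificity = mean(spec)),
            class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  print(x$confusion)
  cat("sensitivity:", paste(names(x$sensitivity),
                            round(x$sensitivity, 3), collapse = "  "), "\n")
  cat("specificity:", paste(names(x$specificity),
                            round(x$specificity, 3), collapse = "  "), "\n")
  cat(sprintf("overall (macro): sensitivity %.3f, specificity %.3f\n",
              x$overall_sensitivity, x$overall_specificity))
  invisible(x)
}

#' Leave-one-out cross-validated PLS-DA evaluation
#'
#' Refits the PLS-DA model with each spectrum held out in turn and
#' reports the multiclass metrics of the held-out predictions.
#'
#' @param set a preprocessed `raman_set`.
#' @param k latent variables per fit.
#' @return list with `predictions` (factor) and `report`
#'   (a [multiclass_metrics()] result).
#' @export
raman_loo_cv <- function(set, k = 4L) {
  n <- nrow(set$X)
  preds <- character(n)
  for (i in seq_len(n)) {
    tr <- structure(list(axis = set$axis, X = set$X[-i, , drop = FALSE],
                         labels = set$labels[-i],
                         preprocessing = set$preprocessing),
                    class = "raman_set")
    m <- plsda_fit(tr, k = k)
    preds[i] <- as.character(plsda_predict(m, set$X[i, , drop = FALSE]))
  }
  preds <- factor(preds, levels = levels(factor(set$labels)))
  list(predictions = preds, report = multiclass_metrics(preds, set$labels))
}

#' Locate the most prominent peaks of an LV loading
#'
#' Finds strict local maxima of the absolute loading within a wavenumber
#' window and returns them sorted by magnitude.
#'
#' @param model a [plsda_fit()] model.
#' @param which latent variable, e.g. `"LV1"`.
#' @param window wavenumber range to search (default the fingerprint
#'   region, 600-1800 cm-1).
#' @param n_peaks number of top peaks to return.
#' @return data.frame with `wavenumber` and `magnitude`, ordered by
#'   decreasing magnitude.
#' @export
loading_peaks <- function(model, which = "LV1", window = c(600, 1800),
                          n_peaks = 2L) {
  sl <- plsda_scores_loadings(model, which)
  v <- abs(sl$loadings)
  ax <- sl$axis
  inw <- ax >= window[1] & ax <= window[2]
  idx <- which(inw)
  loc <- idx[idx > 1 & idx < length(ax)]
  is_peak <- v[loc] > v[loc - 1L] & v[loc] > v[loc + 1L]
  pk <- loc[is_peak]
  pk <- pk[order(v[pk], decreasing = TRUE)]
  pk <- head(pk, n_peaks)
  data.frame(wavenumber = ax[pk], magnitude = v[pk])
}
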