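#' Feature-selection configuration
#'
#' The default retains the nine top-ranked mRMR features per fold. The
#' `d ~ sqrt(n)` guidance relating selected-feature count to training
#' sample size is surfaced as a message when strongly violated, but never
#' enforced.
#'
#' @param d number of selected features (default 9).
#' @param n training sample count (optional, for the guidance check).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(d = 9L, n = NULL) {
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be >= 1")
  if (!is.null(n) && abs(d - sqrt(n)) > sqrt(n))
    message("selected feature count d = ", d,
            " is far from the d ~ sqrt(n) guidance (sqrt(n) = ",
            round(sqrt(n), 1), ")")
  structure(list(d = d, n = n, ranking = "mrmr"),
            class = "selection_config")
}

# ---- classifier roster -----------------------------------------------------
# Each roster member is a fit function (x, y, seed) -> object with a
# $prob(newx) method returning P(pathologic).  Inputs are standardized by
# the ensemble before they reach the members.

fit_logistic_ridge <- function(x, y, seed) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 0.01, standardize = FALSE)
  list(prob = function(newx)
    as.numeric(predict(fit, newx, type = "response")))
}

fit_random_forest <- function(x, y, seed) {
  fit <- with_seed(seed, randomForest::randomForest(x, y, ntree = 200L))
  list(prob = function(newx)
    as.numeric(predict(fit, newx, type = "prob")[, "pathologic"]))
}

fit_knn <- function(x, y, seed, k = 5L) {
  list(prob = function(newx) {
    pr <- class::knn(x, newx, y, k = k, prob = TRUE)
    p <- attr(pr, "prob")
    ifelse(pr == "pathologic", p, 1 - p)
  })
}

fit_svm_rbf <- function(x, y, seed) {
  fit <- with_seed(seed, e1071::svm(x, y, kernel = "radial",
                                    probability = TRUE, scale = FALSE))
  list(prob = function(newx) {
    pp <- attr(predict(fit, newx, probability = TRUE), "probabilities")
    as.numeric(pp[, "pathologic"])
  })
}

#' Default classifier roster
#'
#' Four distinct supervised families forming the voting committee: a
#' ridge-regularized logistic model, a random forest, a k-nearest-neighbor
#' voter and an RBF-kernel support vector machine with probability
#' calibration. All emit a probability for the pathologic class.
#'
#' @return named list of fit functions.
#' @export
default_roster <- function()
  list(logistic_ridge = fit_logistic_ridge,
       random_forest = fit_random_forest,
       knn = fit_knn,
       svm_rbf = fit_svm_rbf)

# ---- ensemble --------------------------------------------------------------

binary_factor <- function(y)
  factor(as.character(y), levels = c("healthy", "pathologic"))

#' Train the classifier ensemble on one Monte-Carlo fold
#'
#' Pipeline order per fold: mRMR ranking of the fold's *training* rows
#' selects the top `cfg$d` features; SMOTE balances the training rows;
#' features are standardized; every roster member is fitted. Feature
#' selection and SMOTE never see validation rows.
#'
#' @param fold one fold from [build_mc_folds()].
#' @param table a `feature_table` (training cohort).
#' @param cfg a [selection_config()].
#' @param roster classifier roster, see [default_roster()].
#' @param seed integer seed for SMOTE and stochastic learners.
#' @return list of class `ensemble_model`: `selected` (feature names),
#'   `center`/`scale`, fitted `members`, `fold_id`.
#' @export
train_ensemble <- function(fold, table, cfg = selection_config(),
                           roster = default_roster(), seed = 1L) {
  feats <- feature_columns(table)
  if (cfg$d > length(feats)) stop("cfg$d exceeds the feature count")
  tr <- table[fold$train, , drop = FALSE]
  y <- as.character(tr$binary_label)
  if (length(unique(y)) < 2L) stop("degenerate training data: single class")
  x <- as.matrix(tr[, feats, drop = FALSE])
  selected <- mrmr_rank(x, y, d = cfg$d)
  xs <- x[, selected, drop = FALSE]
  bal <- smote_balance(xs, y, k_neighbors = 5L,
                       seed = derive_seed(seed, 3L, fold$fold_id))
  ctr <- colMeans(bal$x)
  scl <- apply(bal$x, 2, sd)
  scl[scl == 0] <- 1
  xz <- scale(bal$x, ctr, scl)
  yf <- binary_factor(bal$y)
  members <- lapply(seq_along(roster), function(m)
    roster[[m]](xz, yf, seed = derive_seed(seed, 4L,
                                           fold$fold_id * 100L + m)))
  names(members) <- names(roster)
  structure(list(selected = selected, center = ctr, scale = scl,
                 members = members, fold_id = fold$fold_id),
            class = "ensemble_model")
}

# per-classifier pathologic probabilities of one ensemble on new data
ensemble_probs <- function(model, table) {
  x <- as.matrix(table[, model$selected, drop = FALSE])
  xz <- scale(x, model$center, model$scale)
  vapply(model$members, function(m) m$prob(xz), numeric(nrow(xz)))
}

#' Aggregate committee predictions
#'
#' Collects the pathologic probability of every classifier from every
#' fold's ensemble, takes the majority vote over per-classifier votes
#' (probability >= 0.5), and the mean probability `rho` per plane. A tied
#' vote is resolved pathologic iff `rho >= 0.5`.
#'
#' @param models list of `ensemble_model` objects (one per fold).
#' @param table `feature_table` with the planes to predict.
#' @return data.frame of class `prediction_result`: `plane_id`, `vote`,
#'   `rho`, plus the per-classifier probability matrix as attribute
#'   `"probs"`.
#' @export
predict_mpm <- function(models, table) {
  if (length(models) < 1L) stop("at least one fitted ensemble required")
  P <- do.call(cbind, lapply(models, ensemble_probs, table = table))
  rho <- rowMeans(P)
  votes <- rowMeans(P >= 0.5)
  vote <- ifelse(votes > 0.5, "pathologic",
                 ifelse(votes < 0.5, "healthy",
                        ifelse(rho >= 0.5, "pathologic", "healthy")))
  out <- data.frame(plane_id = table$plane_id, vote = vote, rho = rho,
                    stringsAsFactors = FALSE)
  attr(out, "probs") <- P
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Binary performance metrics
#'
#' Confusion counts and accuracy, sensitivity, specificity with
#' pathologic as the positive class.
#'
#' @param predicted,truth binary labels (`"healthy"` / `"pathologic"`).
#' @return list with `tp`, `fn`, `tn`, `fp`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
score_binary <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("label length mismatch")
  ok <- c("healthy", "pathologic")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be healthy/pathologic")
  tp <- sum(predicted == "pathologic" & truth == "pathologic")
  fn <- sum(predicted == "healthy" & truth == "pathologic")
  tn <- sum(predicted == "healthy" & truth == "healthy")
  fp <- sum(predicted == "pathologic" & truth == "healthy")
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Run the full Monte-Carlo training and evaluation
#'
#' Builds folds, trains one ensemble per fold, scores each fold's
#' validation set, pools the fold-level confusion counts, and (optionally)
#' predicts and scores a test cohort with the aggregated committee.
#'
#' @param train_table training `feature_table`.
#' @param test_table optional test `feature_table`.
#' @param cfg a [selection_config()].
#' @param n_folds number of Monte-Carlo folds.
#' @param roster classifier roster.
#' @param seed integer root seed.
#' @return list with `models`, `folds`, `fold_metrics` (data.frame),
#'   `pooled` (metrics over pooled fold confusions), and when a test
#'   table is given: `test_predictions`, `test_metrics`.
#' @export
run_mpm_ml <- function(train_table, test_table = NULL,
                       cfg = selection_config(), n_folds = 20L,
                       roster = default_roster(), seed = 1L) {
  folds <- build_mc_folds(train_table$binary_label, n_folds = n_folds,
                          seed = seed)
  models <- vector("list", length(folds))
  fm <- vector("list", length(folds))
  pooled_counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (k in seq_along(folds)) {
    models[[k]] <- train_ensemble(folds[[k]], train_table, cfg = cfg,
                                  roster = roster, seed = seed)
    val <- train_table[folds[[k]]$validation, , drop = FALSE]
    pred <- predict_mpm(models[k], val)
    s <- score_binary(pred$vote, val$binary_label)
    pooled_counts <- pooled_counts +
      unlist(s[c("tp", "fn", "tn", "fp")])
    fm[[k]] <- data.frame(fold = k, accuracy = s$accuracy,
                          sensitivity = s$sensitivity,
                          specificity = s$specificity)
  }
  pooled <- list(
    tp = pooled_counts["tp"], fn = pooled_counts["fn"],
    tn = pooled_counts["tn"], fp = pooled_counts["fp"],
    accuracy = (pooled_counts["tp"] + pooled_counts["tn"]) /
      sum(pooled_counts),
    sensitivity = pooled_counts["tp"] /
      (pooled_counts["tp"] + pooled_counts["fn"]),
    specificity = pooled_counts["tn"] /
      (pooled_counts["tn"] + pooled_counts["fp"]))
  pooled <- lapply(pooled, unname)
  out <- list(models = models, folds = folds,
              fold_metrics = do.call(rbind, fm), pooled = pooled)
  if (!is.null(test_table)) {
    out$test_predictions <- predict_mpm(models, test_table)
    out$test_metrics <- score_binary(out$test_predictions$vote,
                                     test_table$binary_label)
  }
  out
}
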