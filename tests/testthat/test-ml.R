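# mRMR ranking ---------------------------------------------------------------

test_that("mRMR ranks a label copy first and penalizes redundancy", {
  set.seed(41)
  n <- 60
  y <- rep(c("healthy", "pathologic"), each = n / 2)
  ynum <- as.numeric(factor(y))
  x <- cbind(noise1 = rnorm(n), label_copy = ynum, noise2 = rnorm(n),
             weak = ynum + rnorm(n, 0, 2))
  expect_identical(mrmr_rank(x, y, d = 1), "label_copy")

  # redundancy penalty: a near-duplicate of the best feature loses to a
  # weaker but non-redundant feature on the second pick.  Brute-force
  # greedy scores confirm the ordering.
  set.seed(43)
  strong <- ynum + rnorm(n, 0, 0.1)
  dup <- strong + rnorm(n, 0, 0.01)          # nearly identical information
  weak <- ynum + rnorm(n, 0, 2)              # weak but independent noise
  x2 <- cbind(strong = strong, dup = dup, weak = weak)
  ranked <- mrmr_rank(x2, y, d = 2)
  expect_identical(ranked[1], "strong")
  expect_identical(ranked[2], "weak")
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    s
  }
  qb <- fibroscar:::quantile_bin
  score_dup <- mi(qb(dup), ynum) - mi(qb(dup), qb(strong))
  score_weak <- mi(qb(weak), ynum) - mi(qb(weak), qb(strong))
  expect_gt(score_weak, score_dup)
})

test_that("an exact label duplicate cancels out to a zero greedy score", {
  # with an exact label copy already selected, every candidate's relevance
  # equals its redundancy with that copy, so all second-step scores are
  # exactly zero and the column-order tie-break decides
  set.seed(44)
  n <- 60
  y <- rep(c("healthy", "pathologic"), each = n / 2)
  ynum <- as.numeric(factor(y))
  x2 <- cbind(copy_a = ynum, copy_b = ynum, weak = ynum + rnorm(n, 0, 2))
  ranked <- mrmr_rank(x2, y, d = 2)
  expect_identical(ranked[1], "copy_a")
  expect_identical(ranked[2], "copy_b")    # zero-score tie, column order
  qb <- fibroscar:::quantile_bin
  mi2 <- fibroscar:::mutual_information
  for (f in c("copy_b", "weak"))
    expect_equal(mi2(qb(x2[, f]), as.integer(factor(y))) -
                   mi2(qb(x2[, f]), qb(x2[, "copy_a"])), 0,
                 tolerance = 1e-12)
})

test_that("mRMR ranking is invariant to feature column order", {
  set.seed(42)
  n <- 80
  y <- rep(c("healthy", "pathologic"), each = n / 2)
  x <- sapply(1:6, function(i) as.numeric(factor(y)) * i / 6 + rnorm(n, 0, 1))
  colnames(x) <- paste0("f", 1:6)
  r1 <- mrmr_rank(x, y, d = 4)
  perm <- c(4, 2, 6, 1, 3, 5)
  r2 <- mrmr_rank(x[, perm], y, d = 4)
  expect_setequal(r1, r2)
  expect_error(mrmr_rank(x, rep("healthy", n)), "two classes")
})

# SMOTE -----------------------------------------------------------------------

test_that("SMOTE synthesizes convex combinations on the minority segment", {
  mino <- rbind(c(0, 0), c(2, 2))
  syn <- smote_oversample(mino, k_neighbors = 1, n_synthetic = 20, seed = 1)
  expect_identical(nrow(syn), 20L)
  expect_true(all(syn >= 0 & syn <= 2))
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)  # on the diagonal
  expect_error(smote_oversample(mino[1, , drop = FALSE], 1, 5), "at least 2")
})

test_that("SMOTE balancing yields equal class counts (45 vs 117 case)", {
  set.seed(2)
  x <- matrix(rnorm(162 * 3), 162, 3)
  y <- rep(c("healthy", "pathologic"), c(45, 117))
  bal <- smote_balance(x, y, seed = 4)
  expect_identical(as.integer(table(bal$y)), c(117L, 117L))
  expect_identical(nrow(bal$x), 234L)
  # synthetic rows are coordinatewise within the minority bounding box
  syn <- bal$x[163:234, ]
  rng <- apply(x[y == "healthy", ], 2, range)
  for (j in 1:3) {
    expect_gte(min(syn[, j]), rng[1, j] - 1e-12)
    expect_lte(max(syn[, j]), rng[2, j] + 1e-12)
  }
})

# Monte-Carlo folds -----------------------------------------------------------

test_that("fold arithmetic matches the 56/128 design", {
  y <- rep(c("healthy", "pathologic"), c(56, 128))
  folds <- build_mc_folds(y, n_folds = 10, seed = 3)
  for (f in folds) {
    expect_identical(length(f$validation), 22L)  # 11 per class
    expect_identical(sum(y[f$validation] == "healthy"), 11L)
    expect_identical(sum(y[f$validation] == "pathologic"), 11L)
    expect_identical(length(f$train), 162L)
    expect_identical(length(intersect(f$train, f$validation)), 0L)
  }
  keys <- vapply(folds, function(f) paste(f$validation, collapse = ","), "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("fold edge cases behave as specified", {
  y5 <- rep(c("healthy", "pathologic"), c(5, 20))
  f <- build_mc_folds(y5, n_folds = 2, seed = 1)
  expect_identical(length(f[[1]]$validation), 2L)  # v = 1 per class
  expect_error(build_mc_folds(rep(c("healthy", "pathologic"), c(4, 10)),
                              n_folds = 1), "at least 5")
  expect_error(build_mc_folds(y5, n_folds = 100), "exceeds")
  expect_error(build_mc_folds(rep("healthy", 30), 2), "binary")
})

# ensemble --------------------------------------------------------------------

make_toy_table <- function(n_per_class = 30, p_noise = 6, seed = 5,
                           shift = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c("healthy", "pathologic"), each = n_per_class)
  x <- cbind(sig1 = ifelse(y == "pathologic", shift, 0) + rnorm(n),
             sig2 = ifelse(y == "pathologic", -shift, 0) + rnorm(n),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  out <- cbind(data.frame(plane_id = sprintf("p%03d", seq_len(n)),
                          roi_id = "ROI1", tissue_class = y,
                          binary_label = y), as.data.frame(x))
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("the ensemble separates a strongly separated cohort", {
  tab <- make_toy_table()
  folds <- build_mc_folds(tab$binary_label, n_folds = 4, seed = 7)
  for (f in folds[1:2]) {
    m <- train_ensemble(f, tab, selection_config(d = 3), seed = 7)
    val <- tab[f$validation, ]
    pred <- predict_mpm(list(m), val)
    s <- score_binary(pred$vote, val$binary_label)
    expect_gte(s$accuracy, 0.9)
  }
})

test_that("training is deterministic and never sees validation rows", {
  tab <- make_toy_table()
  folds <- build_mc_folds(tab$binary_label, n_folds = 2, seed = 9)
  f <- folds[[1]]
  m1 <- train_ensemble(f, tab, selection_config(d = 3), seed = 11)
  m2 <- train_ensemble(f, tab, selection_config(d = 3), seed = 11)
  expect_identical(m1$selected, m2$selected)
  p1 <- predict_mpm(list(m1), tab)
  p2 <- predict_mpm(list(m2), tab)
  expect_equal(p1$rho, p2$rho, tolerance = 1e-12)
  # corrupt every validation row: the fitted ensemble must not change
  tab2 <- tab
  feats <- feature_columns(tab)
  tab2[f$validation, feats] <- 1e6
  m3 <- train_ensemble(f, tab2, selection_config(d = 3), seed = 11)
  expect_identical(m3$selected, m1$selected)
  expect_equal(predict_mpm(list(m3), tab)$rho, p1$rho, tolerance = 1e-12)
})

test_that("d equal to the full feature count is a reordering, not a cut", {
  tab <- make_toy_table()
  folds <- build_mc_folds(tab$binary_label, n_folds = 1, seed = 2)
  m <- train_ensemble(folds[[1]], tab,
                      selection_config(d = length(feature_columns(tab))),
                      seed = 1)
  expect_setequal(m$selected, feature_columns(tab))
})

test_that("vote aggregation follows majority, mean rho and the tie rule", {
  fake_model <- function(probs) {
    structure(list(selected = "sig1", center = c(sig1 = 0),
                   scale = c(sig1 = 1),
                   members = lapply(probs, function(p)
                     list(prob = function(newx) rep(p, nrow(newx)))),
                   fold_id = 1L),
              class = "ensemble_model")
  }
  tab <- make_toy_table(n_per_class = 2)
  pred <- predict_mpm(list(fake_model(c(0.9, 0.8, 0.1))), tab)
  expect_identical(unique(pred$vote), "pathologic")      # 2 of 3 votes
  expect_equal(unique(pred$rho), mean(c(0.9, 0.8, 0.1)), tolerance = 1e-12)
  pred2 <- predict_mpm(list(fake_model(c(0.9, 0.8, 1.0))), tab)
  expect_equal(unique(pred2$rho), 0.9, tolerance = 1e-12)
  # all probabilities exactly 0.5 with an even roster: tie -> pathologic
  pred3 <- predict_mpm(list(fake_model(c(0.5, 0.5))), tab)
  expect_identical(unique(pred3$vote), "pathologic")
})

test_that("binary scoring computes the three metrics from confusions", {
  pred <- rep(c("pathologic", "healthy", "healthy", "pathologic"),
              c(9, 1, 9, 1))
  truth <- rep(c("pathologic", "healthy"), each = 10)
  s <- score_binary(pred, truth)
  expect_equal(s$accuracy, 0.9)
  expect_equal(s$sensitivity, 0.9)
  expect_equal(s$specificity, 0.9)
  perfect <- score_binary(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  allpath <- score_binary(rep("pathologic", 22),
                          rep(c("pathologic", "healthy"), each = 11))
  expect_equal(allpath$sensitivity, 1)
  expect_equal(allpath$specificity, 0)
  expect_equal(allpath$accuracy, 0.5)
})

test_that("scrambled labels drive pooled accuracy to chance", {
  tab <- make_toy_table(n_per_class = 40)
  set.seed(13)
  tab$binary_label <- sample(tab$binary_label)
  tab$tissue_class <- tab$binary_label
  res <- run_mpm_ml(tab, cfg = selection_config(d = 3), n_folds = 8,
                    seed = 13)
  expect_lt(abs(res$pooled$accuracy - 0.5), 0.15)
})
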