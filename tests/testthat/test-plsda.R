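# eigen/svd-based PLS2 oracle: at each deflation step the NIPALS weight
# vector is the dominant left singular vector of X'Y.
oracle_pls <- function(X, Y, k) {
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  W <- matrix(0, ncol(X), k); Tm <- matrix(0, nrow(X), k)
  P <- matrix(0, ncol(X), k)
  for (a in seq_len(k)) {
    sv <- svd(crossprod(X, Y))
    w <- sv$u[, 1]
    t_ <- X %*% w
    p_ <- crossprod(X, t_) / sum(t_^2)
    q_ <- crossprod(Y, t_) / sum(t_^2)
    W[, a] <- w; Tm[, a] <- t_; P[, a] <- p_
    X <- X - t_ %*% t(p_)
    Y <- Y - t_ %*% t(q_)
  }
  list(W = W, T = Tm, P = P)
}

toy_set <- function(n_per_class = 12, p = 40, noise = 0.05, seed = 3) {
  set.seed(seed)
  classes <- raman_classes()
  centers <- matrix(rnorm(4 * p, sd = 1), 4, p)
  X <- centers[rep(1:4, each = n_per_class), ] +
    matrix(rnorm(4 * n_per_class * p, sd = noise), 4 * n_per_class, p)
  structure(list(axis = seq_len(p), X = X,
                 labels = factor(rep(classes, each = n_per_class),
                                 levels = classes),
                 preprocessing = character(0)),
            class = "raman_set")
}

test_that("NIPALS components match the svd-based PLS2 oracle", {
  set.seed(1)
  st <- toy_set()
  m <- plsda_fit(st, k = 3)
  Y <- outer(as.character(st$labels), m$classes, `==`) * 1.0
  or <- oracle_pls(st$X, Y, 3)
  for (a in 1:3) {
    # match up to sign
    s <- sign(sum(m$weights[, a] * or$W[, a]))
    expect_equal(m$weights[, a], s * or$W[, a], tolerance = 1e-8)
    expect_equal(m$scores[, a], s * or$T[, a], tolerance = 1e-8)
    expect_equal(m$loadings[, a], s * or$P[, a], tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and X variance decreases per component", {
  st <- toy_set(seed = 5)
  m <- plsda_fit(st, k = 4)
  G <- crossprod(m$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  expect_true(all(diff(m$x_var) <= 1e-8))
  expect_error(plsda_fit(st, k = 1000), "too large")
})

test_that("a single discriminating channel dominates the LV1 weight", {
  p <- 30
  X <- matrix(0, 20, p)
  lab <- rep(c("muscle", "fibrotic"), each = 10)
  X[lab == "fibrotic", 17] <- 1   # the only informative channel
  st <- structure(list(axis = seq_len(p), X = X,
                       labels = factor(lab, levels = raman_classes()),
                       preprocessing = character(0)), class = "raman_set")
  m <- plsda_fit(st, k = 1)
  w <- abs(m$weights[, 1])
  expect_identical(which.max(w), 17L)
  expect_true(all(w[-17] < 1e-6 * w[17]))
})

test_that("prediction recovers a noiseless separable fixture exactly", {
  st <- toy_set(noise = 0)
  m <- plsda_fit(st, k = 4)
  pred <- plsda_predict(m, st)
  expect_identical(as.character(pred), as.character(st$labels))
  # a class mean maps to its class
  mu <- colMeans(st$X[st$labels == "granulated", ])
  expect_identical(as.character(plsda_predict(m, matrix(mu, 1))),
                   "granulated")
  expect_error(plsda_predict(m, matrix(0, 1, 7)), "mismatch")
})

test_that("score/loading accessors check component availability", {
  st <- toy_set()
  m2 <- plsda_fit(st, k = 2)
  sl <- plsda_scores_loadings(m2, "LV2")
  expect_identical(length(sl$loadings), ncol(st$X))
  expect_identical(length(sl$scores), nrow(st$X))
  m1 <- plsda_fit(st, k = 1)
  expect_error(plsda_scores_loadings(m1, "LV2"), "not available")
})

test_that("LV1/LV2 span is stable under class relabeling", {
  st <- toy_set(seed = 9)
  m <- plsda_fit(st, k = 2)
  perm <- c("fibrotic", "muscle", "granulated", "necrotic")
  st2 <- st
  st2$labels <- factor(perm[as.integer(st$labels)], levels = levels(st$labels))
  m2 <- plsda_fit(st2, k = 2)
  # principal angles between the two (LV1, LV2) weight subspaces
  q1 <- qr.Q(qr(m$weights)); q2 <- qr.Q(qr(m2$weights))
  angles <- acos(pmin(1, svd(crossprod(q1, q2))$d))
  expect_lt(max(angles), 0.2)
})

test_that("multiclass metrics follow the confusion arithmetic", {
  truth <- factor(rep(raman_classes(), each = 10),
                  levels = raman_classes())
  pred <- as.character(truth)
  pred[1] <- "necrotic"   # one muscle plane mislabeled necrotic
  rep_ <- multiclass_metrics(pred, truth)
  expect_equal(unname(rep_$sensitivity["muscle"]), 0.9)
  expect_equal(unname(rep_$specificity["necrotic"]), 29 / 30, tolerance = 1e-12)
  perfect <- multiclass_metrics(truth, truth)
  expect_true(all(perfect$sensitivity == 1) && all(perfect$specificity == 1))
  const <- multiclass_metrics(rep("muscle", 40), truth)
  expect_equal(unname(const$sensitivity["muscle"]), 1)
  expect_equal(unname(const$specificity["muscle"]), 0)
  expect_error(multiclass_metrics(rep("scar", 40), truth), "unseen")
})

test_that("LOO cross-validation recovers separable toy classes", {
  st <- toy_set(n_per_class = 8, noise = 0.1)
  cv <- raman_loo_cv(st, k = 4)
  expect_gte(cv$report$overall_sensitivity, 0.9)
  expect_gte(cv$report$overall_specificity, 0.9)
})
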