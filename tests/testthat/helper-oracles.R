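# Independent brute-force oracles for the texture features: everything is
# computed with explicit per-pixel / per-entry loops, never through the
# package's vectorized builders or formula code.

oracle_fixture <- function(h, w, n_levels, mask_frac = 0.8) {
  lev <- matrix(sample.int(n_levels, h * w, replace = TRUE), h, w)
  msk <- matrix(runif(h * w) < mask_frac, h, w)
  if (!any(msk)) msk[sample.int(h * w, 1)] <- TRUE
  lev[!msk] <- 0L
  structure(list(levels = lev, n_levels = n_levels, mask = msk),
            class = "discretized_image")
}

oracle_glcm <- function(d) {
  L <- d$levels; Ng <- d$n_levels
  H <- nrow(L); W <- ncol(L)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  M <- matrix(0, Ng, Ng)
  for (r in 1:H) for (c in 1:W) {
    if (L[r, c] == 0) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (L[r2, c2] == 0) next
      M[L[r, c], L[r2, c2]] <- M[L[r, c], L[r2, c2]] + 1
      M[L[r2, c2], L[r, c]] <- M[L[r2, c2], L[r, c]] + 1
    }
  }
  if (sum(M) > 0) M / sum(M) else M
}

oracle_glrlm <- function(d, directions = c("0", "45", "90", "135")) {
  L <- d$levels; Ng <- d$n_levels
  H <- nrow(L); W <- ncol(L)
  M <- matrix(0, Ng, max(H, W))
  steps <- list(`0` = c(0, 1), `90` = c(1, 0), `45` = c(-1, 1),
                `135` = c(-1, -1))
  for (dir in directions) {
    st <- steps[[dir]]
    # starts: all pixels with no predecessor along the step
    for (r in 1:H) for (c in 1:W) {
      pr <- r - st[1]; pc <- c - st[2]
      if (pr >= 1 && pr <= H && pc >= 1 && pc <= W) next  # not a line start
      # walk the line
      rr <- r; cc <- c
      run_lev <- 0; run_len <- 0
      while (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        v <- L[rr, cc]
        if (v == run_lev && v > 0) {
          run_len <- run_len + 1
        } else {
          if (run_lev > 0) M[run_lev, run_len] <- M[run_lev, run_len] + 1
          run_lev <- v; run_len <- if (v > 0) 1 else 0
        }
        rr <- rr + st[1]; cc <- cc + st[2]
      }
      if (run_lev > 0) M[run_lev, run_len] <- M[run_lev, run_len] + 1
    }
  }
  M
}

oracle_ngldm <- function(d, alpha = 0) {
  L <- d$levels; msk <- d$mask; Ng <- d$n_levels
  H <- nrow(L); W <- ncol(L)
  M <- matrix(0, Ng, 9)
  for (r in 1:H) for (c in 1:W) {
    if (!msk[r, c]) next
    j <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (msk[r2, c2] && abs(L[r2, c2] - L[r, c]) <= alpha) j <- j + 1
    }
    M[L[r, c], j] <- M[L[r, c], j] + 1
  }
  M
}

oracle_ngtdm <- function(d) {
  L <- d$levels; msk <- d$mask; Ng <- d$n_levels
  H <- nrow(L); W <- ncol(L)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (r in 1:H) for (c in 1:W) {
    if (!msk[r, c]) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (msk[r2, c2]) nb <- c(nb, L[r2, c2])
    }
    if (length(nb) == 0) next
    i <- L[r, c]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  nvc <- sum(n_i)
  list(n = n_i, p = if (nvc > 0) n_i / nvc else n_i, s = s_i, n_valid = nvc)
}

# 8-connected zones by BFS flood fill; returns per-zone (level, size,
# min city-block distance to outside-the-mask).
oracle_zones <- function(d) {
  L <- d$levels; msk <- d$mask
  H <- nrow(L); W <- ncol(L)
  # brute-force city-block distance for every mask pixel
  dist <- matrix(Inf, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (!msk[r, c]) next
    best <- min(r, c, H - r + 1, W - c + 1)  # to outside the image
    for (r2 in 1:H) for (c2 in 1:W)
      if (!msk[r2, c2]) best <- min(best, abs(r - r2) + abs(c - c2))
    dist[r, c] <- best
  }
  seen <- matrix(FALSE, H, W)
  zones <- list()
  for (r in 1:H) for (c in 1:W) {
    if (!msk[r, c] || seen[r, c]) next
    lev <- L[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    px <- list()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      px[[length(px) + 1]] <- cur
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
        if (!seen[r2, c2] && msk[r2, c2] && L[r2, c2] == lev) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    dmin <- min(vapply(px, function(p) dist[p[1], p[2]], numeric(1)))
    zones[[length(zones) + 1]] <- c(level = lev, size = length(px),
                                    dist = dmin)
  }
  do.call(rbind, zones)
}

# family features (run-length style) from explicit sums over a count
# matrix with column index j interpreted as the magnitude
oracle_family_features <- function(M, jvals, n_valid) {
  N <- sum(M)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  mu_i <- mu_j <- 0
  for (i in seq_len(nrow(M))) for (jj in seq_along(jvals)) {
    n <- M[i, jj]; j <- jvals[jj]
    if (n == 0) next
    sre <- sre + n / j^2;        lre <- lre + n * j^2
    lgre <- lgre + n / i^2;      hgre <- hgre + n * i^2
    srlge <- srlge + n / (i^2 * j^2); srhge <- srhge + n * i^2 / j^2
    lrlge <- lrlge + n * j^2 / i^2;  lrhge <- lrhge + n * i^2 * j^2
    mu_i <- mu_i + (n / N) * i;  mu_j <- mu_j + (n / N) * j
  }
  glv <- rlv <- ent <- 0
  for (i in seq_len(nrow(M))) for (jj in seq_along(jvals)) {
    n <- M[i, jj]
    if (n == 0) next
    p <- n / N
    glv <- glv + p * (i - mu_i)^2
    rlv <- rlv + p * (jvals[jj] - mu_j)^2
    ent <- ent - p * log2(p)
  }
  gl_marg <- rowSums(M); j_marg <- colSums(M)
  c(sre = sre / N, lre = lre / N, lgre = lgre / N, hgre = hgre / N,
    srlge = srlge / N, srhge = srhge / N, lrlge = lrlge / N,
    lrhge = lrhge / N,
    glnu = sum(gl_marg^2) / N, glnu.norm = sum(gl_marg^2) / N^2,
    rlnu = sum(j_marg^2) / N, rlnu.norm = sum(j_marg^2) / N^2,
    r.perc = N / n_valid, gl.var = glv, rl.var = rlv, rl.entr = ent)
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  mu <- 0
  for (i in 1:Ng) for (j in 1:Ng) mu <- mu + i * P[i, j]
  sig2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  px <- rowSums(P)
  jm <- ja <- jv <- je <- en <- ct <- ds <- id <- idn <- idm <- idmn <- 0
  iv <- corr_num <- ac <- clt <- cls <- clp <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    jm <- max(jm, p)
    ja <- ja + i * p
    if (p > 0) je <- je - p * log2(p)
    en <- en + p^2
    ct <- ct + (i - j)^2 * p
    ds <- ds + abs(i - j) * p
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / Ng)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / Ng^2)
    if (i != j) iv <- iv + p / (i - j)^2
    corr_num <- corr_num + (i - mu) * (j - mu) * p
    ac <- ac + i * j * p
    clt <- clt + (i + j - 2 * mu)^2 * p
    cls <- cls + (i + j - 2 * mu)^3 * p
    clp <- clp + (i + j - 2 * mu)^4 * p
  }
  for (i in 1:Ng) for (j in 1:Ng) jv <- jv + (i - ja)^2 * P[i, j]
  pd <- numeric(Ng); ps <- numeric(2 * Ng - 1)
  for (i in 1:Ng) for (j in 1:Ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  dk <- 0:(Ng - 1); sk <- 2:(2 * Ng)
  mud <- sum(dk * pd); mus <- sum(sk * ps)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy1 <- hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pp <- px[i] * px[j]
    if (P[i, j] > 0 && pp > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
    if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
  }
  c(joint.max = jm, joint.avg = mu, joint.var = sig2, joint.entr = je,
    diff.avg = mud, diff.var = sum((dk - mud)^2 * pd), diff.entr = de,
    sum.avg = mus, sum.var = sum((sk - mus)^2 * ps), sum.entr = se,
    energy = en, contrast = ct, dissimilarity = ds, inv.diff = id,
    inv.diff.norm = idn, inv.diff.mom = idm, inv.diff.mom.norm = idmn,
    inv.var = iv,
    corr = if (sig2 > 0) corr_num / sig2 else 1,
    auto.corr = ac, clust.tend = clt, clust.shade = cls, clust.prom = clp,
    info.corr.1 = if (hx > 0) (je - hxy1) / hx else 0,
    info.corr.2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - je)))))
}

oracle_ngtdm_features <- function(ng, eps = 1e-12) {
  lev <- which(ng$p > 0)
  Np <- length(lev); Nvc <- ng$n_valid
  co <- 0
  for (i in lev) co <- co + ng$p[i] * ng$s[i]
  coarseness <- 1 / (eps + co)
  ctr <- 0
  if (Np > 1) {
    for (i in lev) for (j in lev) ctr <- ctr + ng$p[i] * ng$p[j] * (i - j)^2
    ctr <- ctr / (Np * (Np - 1)) * sum(ng$s) / Nvc
  }
  den <- 0
  for (i in lev) for (j in lev) den <- den + abs(i * ng$p[i] - j * ng$p[j])
  busy <- if (Np > 1) co / (eps + den) else 0
  cplx <- 0
  for (i in lev) for (j in lev)
    cplx <- cplx + abs(i - j) * (ng$p[i] * ng$s[i] + ng$p[j] * ng$s[j]) /
      (ng$p[i] + ng$p[j])
  cplx <- if (Nvc > 0) cplx / Nvc else 0
  st <- 0
  for (i in lev) for (j in lev) st <- st + (ng$p[i] + ng$p[j]) * (i - j)^2
  strength <- st / (eps + sum(ng$s))
  c(coarseness = coarseness, contrast = ctr, busyness = busy,
    complexity = cplx, strength = strength)
}

oracle_local_peak <- function(img, msk, radius) {
  H <- nrow(img); W <- ncol(img)
  best <- -Inf; br <- bc <- 1
  for (r in 1:H) for (c in 1:W) {       # row-major scan keeps first max
    if (msk[r, c] && img[r, c] > best) { best <- img[r, c]; br <- r; bc <- c }
  }
  vals <- c()
  for (r in 1:H) for (c in 1:W)
    if (msk[r, c] && (r - br)^2 + (c - bc)^2 <= radius^2)
      vals <- c(vals, img[r, c])
  mean(vals)
}

oracle_global_peak <- function(img, msk, radius) {
  H <- nrow(img); W <- ncol(img)
  best <- -Inf
  for (r in 1:H) for (c in 1:W) {
    if (!msk[r, c]) next
    vals <- c()
    for (r2 in 1:H) for (c2 in 1:W)
      if (msk[r2, c2] && (r2 - r)^2 + (c2 - c)^2 <= radius^2)
        vals <- c(vals, img[r2, c2])
    best <- max(best, mean(vals))
  }
  best
}

# full cross-check of one random fixture against every brute-force oracle
check_fixture_against_oracles <- function(d, tol = 1e-10) {
  nv <- sum(d$mask)
  # GLCM: matrix and all 25 features
  P_o <- oracle_glcm(d)
  expect_equal(compute_glcm(d), P_o, tolerance = tol)
  expect_equal(glcm_features(compute_glcm(d)), oracle_glcm_features(P_o),
               tolerance = tol)
  # GLRLM: merged matrix and the 16-feature family
  M_o <- oracle_glrlm(d)
  M_i <- compute_glrlm(d)
  expect_equal(M_i[, seq_len(ncol(M_o)), drop = FALSE], M_o, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(unname(glrlm_features(M_i, nv)),
               unname(oracle_family_features(M_o, seq_len(ncol(M_o)), nv)),
               tolerance = tol)
  expect_equal(feature_sre(M_i),
               unname(oracle_family_features(M_o, seq_len(ncol(M_o)), nv)["sre"]),
               tolerance = tol)
  # NGLDM
  S_o <- oracle_ngldm(d)
  S_i <- compute_ngldm(d)
  expect_equal(S_i, S_o, tolerance = 0, ignore_attr = TRUE)
  expect_equal(unname(ngldm_features(S_i, nv)[1:16]),
               unname(oracle_family_features(S_o, seq_len(ncol(S_o)), nv)),
               tolerance = tol)
  expect_equal(feature_hdhge(S_i, nv),
               unname(oracle_family_features(S_o, seq_len(ncol(S_o)), nv)["lrhge"]),
               tolerance = tol)
  # NGTDM
  ng_o <- oracle_ngtdm(d)
  ng_i <- compute_ngtdm(d)
  expect_equal(ng_i$s, ng_o$s, tolerance = tol)
  expect_equal(ng_i$p, ng_o$p, tolerance = tol)
  expect_equal(unname(ngtdm_features(ng_i)),
               unname(oracle_ngtdm_features(ng_o)), tolerance = tol)
  expect_equal(feature_texture_strength(ng_i),
               unname(oracle_ngtdm_features(ng_o)["strength"]),
               tolerance = tol)
  # GLSZM / GLDZM from BFS-flood-fill zones and brute-force distances
  zo <- oracle_zones(d)
  zi <- compute_zone_matrices(d)
  to_mat <- function(i, j, jmax, Ng) {
    M <- matrix(0, Ng, jmax)
    for (r in seq_along(i)) M[i[r], j[r]] <- M[i[r], j[r]] + 1
    M
  }
  jmax_s <- max(zo[, "size"], zi$szm$j)
  Ms_o <- to_mat(zo[, "level"], zo[, "size"], jmax_s, d$n_levels)
  expect_equal(unname(glszm_features(zi, nv)),
               unname(oracle_family_features(Ms_o, seq_len(jmax_s), nv)),
               tolerance = tol)
  jmax_d <- max(zo[, "dist"], zi$dzm$j)
  Md_o <- to_mat(zo[, "level"], zo[, "dist"], jmax_d, d$n_levels)
  expect_equal(unname(gldzm_features(zi, nv)),
               unname(oracle_family_features(Md_o, seq_len(jmax_d), nv)),
               tolerance = tol)
  invisible(TRUE)
}
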