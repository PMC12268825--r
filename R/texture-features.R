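# IBSI texture feature formulas.  Matrix-family features (GLRLM, GLSZM,
# GLDZM, NGLDM) share one generic implementation over triplet counts
# (i = gray level, j = run length / zone size / zone distance / dependence
# count, n = count); GLCM and NGTDM have their own formula sets.

glrlm_to_triplets <- function(M) {
  nz <- which(M > 0, arr.ind = TRUE)
  data.frame(i = nz[, 1], j = nz[, 2], n = M[nz])
}

# The 16 standard (level, magnitude) matrix features.  `eps` guards logs.
family_features <- function(trip, n_valid) {
  i <- trip$i; j <- trip$j; n <- trip$n
  N <- sum(n)
  if (N <= 0) stop("empty texture matrix")
  p <- n / N
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  gl_marg <- rowsum(n, group = i)[, 1]
  j_marg <- rowsum(n, group = j)[, 1]
  c(sre       = sum(n / j^2) / N,
    lre       = sum(n * j^2) / N,
    lgre      = sum(n / i^2) / N,
    hgre      = sum(n * i^2) / N,
    srlge     = sum(n / (i^2 * j^2)) / N,
    srhge     = sum(n * i^2 / j^2) / N,
    lrlge     = sum(n * j^2 / i^2) / N,
    lrhge     = sum(n * i^2 * j^2) / N,
    glnu      = sum(gl_marg^2) / N,
    glnu.norm = sum(gl_marg^2) / N^2,
    rlnu      = sum(j_marg^2) / N,
    rlnu.norm = sum(j_marg^2) / N^2,
    r.perc    = N / n_valid,
    gl.var    = sum(p * (i - mu_i)^2),
    rl.var    = sum(p * (j - mu_j)^2),
    rl.entr   = -sum(p * log2(p)))
}

#' GLRLM feature set (16 features)
#'
#' Short/long runs emphasis, gray-level and run-length non-uniformity,
#' run percentage, variances and run entropy, per IBSI definitions.
#'
#' @param glrlm count matrix from [compute_glrlm()].
#' @param n_valid in-mask pixel count (for run percentage).
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(glrlm, n_valid) {
  if (sum(glrlm) == 0) stop("empty run length matrix")
  family_features(glrlm_to_triplets(glrlm), n_valid)
}

#' Short runs emphasis
#'
#' `SRE = (1/N_r) * sum_{i,j} P(i,j) / j^2`, in (0, 1]; high values
#' indicate fragmented runs (pathologic extracellular-matrix structure in
#' SHG images scores high).
#'
#' @inheritParams glrlm_features
#' @export
feature_sre <- function(glrlm) {
  if (sum(glrlm) == 0) stop("empty run length matrix")
  tr <- glrlm_to_triplets(glrlm)
  sum(tr$n / tr$j^2) / sum(tr$n)
}

#' NGLDM feature set (17 features)
#'
#' Dependence emphases, gray-level/dependence-count non-uniformity,
#' dependence count percentage, variances, entropy and energy.
#'
#' @param ngldm count matrix from [compute_ngldm()].
#' @param n_valid in-mask pixel count.
#' @return named numeric vector of 17 features.
#' @export
ngldm_features <- function(ngldm, n_valid) {
  tr <- glrlm_to_triplets(ngldm)
  f <- family_features(tr, n_valid)
  names(f) <- c("lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge",
                "hdhge", "glnu", "glnu.norm", "dcnu", "dcnu.norm",
                "dc.perc", "gl.var", "dc.var", "dc.entr")
  p <- tr$n / sum(tr$n)
  c(f, dc.energy = sum(p^2))
}

#' High dependence high gray level emphasis
#'
#' `HDHGE = (1/N_v) * sum_{i,j} s(i,j) * i^2 * j^2` with `N_v` the in-mask
#' pixel count; emphasizes bright homogeneous neighborhoods.
#'
#' @inheritParams ngldm_features
#' @export
feature_hdhge <- function(ngldm, n_valid = sum(ngldm)) {
  tr <- glrlm_to_triplets(ngldm)
  sum(tr$n * tr$i^2 * tr$j^2) / n_valid
}

#' NGTDM feature set (5 features)
#'
#' Coarseness, contrast, busyness, complexity, strength per IBSI.
#'
#' @param ngtdm result of [compute_ngtdm()].
#' @param eps tiny positive guard for ratios with vanishing denominators.
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(ngtdm, eps = 1e-12) {
  p <- ngtdm$p; s <- ngtdm$s; n <- ngtdm$n
  lev <- seq_along(p)
  act <- p > 0
  Np <- sum(act)
  Nvc <- ngtdm$n_valid
  i <- lev[act]; pi <- p[act]; si <- s[act]; ni <- n[act]
  ii <- outer(i, i, `-`)
  psum <- outer(pi, pi, `+`)
  coarseness <- 1 / (eps + sum(pi * si))
  contrast <- if (Np > 1)
    (sum(outer(pi, pi) * ii^2) / (Np * (Np - 1))) * (sum(si) / Nvc) else 0
  busyness <- if (Np > 1)
    sum(pi * si) / (eps + sum(abs(outer(i * pi, i * pi, `-`)))) else 0
  complexity <- if (Nvc > 0)
    sum(abs(ii) * outer(pi * si, pi * si, `+`) / psum) / Nvc else 0
  strength <- sum(psum * ii^2) / (eps + sum(si))
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' NGTDM texture strength
#'
#' `strength = sum_{i,j} (p_i + p_j) (i - j)^2 / (eps + sum_i s_i)` over
#' level pairs with non-zero probability; measures large, coarse gray
#' level differences. A single-level image yields 0.
#'
#' @inheritParams ngtdm_features
#' @export
feature_texture_strength <- function(ngtdm, eps = 1e-12)
  unname(ngtdm_features(ngtdm, eps)["strength"])

#' GLSZM / GLDZM feature sets (16 features each)
#'
#' Zone-size (GLSZM) and zone-distance (GLDZM) analogues of the run-length
#' features.
#'
#' @param zones result of [compute_zone_matrices()].
#' @param n_valid in-mask pixel count.
#' @return named numeric vectors of 16 features.
#' @export
glszm_features <- function(zones, n_valid) {
  f <- family_features(zones$szm, n_valid)
  names(f) <- c("sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge",
                "lzhge", "glnu", "glnu.norm", "zsnu", "zsnu.norm", "z.perc",
                "gl.var", "zs.var", "zs.entr")
  f
}

#' @rdname glszm_features
#' @export
gldzm_features <- function(zones, n_valid) {
  f <- family_features(zones$dzm, n_valid)
  names(f) <- c("sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge",
                "ldhge", "glnu", "glnu.norm", "zdnu", "zdnu.norm", "z.perc",
                "gl.var", "zd.var", "zd.entr")
  f
}

#' GLCM feature set (25 features)
#'
#' Joint, difference and sum statistics, energy/contrast/correlation
#' family and the two information measures of correlation, computed from
#' the direction-merged symmetric co-occurrence probability matrix.
#'
#' @param P normalized GLCM from [compute_glcm()].
#' @return named numeric vector of 25 features.
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized")
  Ng <- nrow(P)
  i <- .row(dim(P)); j <- .col(dim(P))
  px <- rowSums(P)
  mu <- sum(i * P)        # symmetric: row mean == col mean == joint average
  sig2 <- sum((i - mu)^2 * P)
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  # difference |i-j| and sum i+j distributions
  dk <- 0:(Ng - 1)
  pd <- vapply(dk, function(k) sum(P[abs(i - j) == k]), numeric(1))
  sk <- 2:(2 * Ng)
  ps <- vapply(sk, function(k) sum(P[(i + j) == k]), numeric(1))
  mud <- sum(dk * pd); mus <- sum(sk * ps)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  # information measures (symmetric P: HX == HY)
  pipj <- outer(px, px)
  ok <- nz & pipj > 0
  hxy1 <- -sum(P[ok] * log2(pipj[ok]))
  hxy2 <- -sum(pipj[pipj > 0] * log2(pipj[pipj > 0]))
  ic1 <- if (hx > 0) (ent - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1
  c(joint.max = max(P),
    joint.avg = mu,
    joint.var = sig2,
    joint.entr = ent,
    diff.avg = mud,
    diff.var = sum((dk - mud)^2 * pd),
    diff.entr = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    sum.avg = mus,
    sum.var = sum((sk - mus)^2 * ps),
    sum.entr = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inv.diff = sum(P / (1 + abs(i - j))),
    inv.diff.norm = sum(P / (1 + abs(i - j) / Ng)),
    inv.diff.mom = sum(P / (1 + (i - j)^2)),
    inv.diff.mom.norm = sum(P / (1 + (i - j)^2 / Ng^2)),
    inv.var = 2 * sum((P / (i - j)^2)[i > j]),
    corr = corr,
    auto.corr = sum(i * j * P),
    clust.tend = sum((i + j - 2 * mu)^2 * P),
    clust.shade = sum((i + j - 2 * mu)^3 * P),
    clust.prom = sum((i + j - 2 * mu)^4 * P),
    info.corr.1 = ic1,
    info.corr.2 = ic2)
}
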