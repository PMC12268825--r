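# Texture count structures (IBSI 2D, "merged" direction aggregation).
#
# All builders take a `discretized_image` (levels 1..Ng inside the mask,
# 0 outside) and return count structures whose conservation invariants
# (run-length-weighted counts = in-mask pixel count, dependence counts =
# in-mask pixel count, GLCM probabilities summing to 1) are tested
# property-style.

glcm_offsets <- function()
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))

#' Gray level co-occurrence matrix (GLCM)
#'
#' Counts in-mask level pairs at Chebyshev distance 1 along the four 2D
#' directions (0, 45, 90, 135 degrees), symmetrized; by default the four
#' directional matrices are merged (summed) and normalized to a joint
#' probability matrix.
#'
#' @param d a [discretize()]d image.
#' @param direction one of `"0"`, `"45"`, `"90"`, `"135"`, or `"merged"`.
#' @param normalize return probabilities (default) or raw counts.
#' @return Ng x Ng numeric matrix.
#' @export
compute_glcm <- function(d, direction = "merged", normalize = TRUE) {
  stopifnot(inherits(d, "discretized_image"))
  A <- d$levels; Ng <- d$n_levels
  H <- nrow(A); W <- ncol(A)
  offs <- glcm_offsets()
  use <- if (identical(direction, "merged")) offs else
    offs[as.character(direction)]
  if (any(vapply(use, is.null, TRUE))) stop("unknown direction")
  M <- matrix(0, Ng, Ng)
  for (o in use) {
    dr <- o[1]; dc <- o[2]
    rs <- max(1L, 1L - dr):min(H, H - dr)
    cs <- max(1L, 1L - dc):min(W, W - dc)
    a <- A[rs, cs]; b <- A[rs + dr, cs + dc]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    tab <- tabulate(a[keep] + Ng * (b[keep] - 1L), nbins = Ng * Ng)
    M <- M + matrix(tab, Ng, Ng)
  }
  M <- M + t(M)  # symmetric pairs
  if (normalize && sum(M) > 0) M <- M / sum(M)
  M
}

# rle over lines of a direction: runs are cut at line boundaries by keying
# each element on (line id, level); out-of-mask pixels (level 0) are
# dropped afterwards.
glrlm_one_direction <- function(A, Ng, direction, r_max) {
  H <- nrow(A); W <- ncol(A)
  r <- .row(dim(A)); c_ <- .col(dim(A))
  key <- switch(as.character(direction),
                `0`   = order(r, c_),
                `90`  = order(c_, r),
                `45`  = order(r + c_, c_),
                `135` = order(c_ - r, c_),
                stop("direction must be one of 0, 45, 90, 135"))
  line <- switch(as.character(direction),
                 `0` = r, `90` = c_, `45` = r + c_, `135` = c_ - r + H)
  v <- A[key]; ln <- line[key]
  rl <- rle(as.numeric(ln) * (Ng + 1) + v)
  lev <- as.integer(rl$values %% (Ng + 1))
  keep <- lev > 0L
  lev <- lev[keep]; len <- rl$lengths[keep]
  tab <- tabulate(lev + Ng * (pmin(len, r_max) - 1L), nbins = Ng * r_max)
  matrix(tab, Ng, r_max)
}

#' Gray level run length matrix (GLRLM)
#'
#' Counts maximal runs of equal gray level along a direction, within the
#' mask only (out-of-mask pixels break runs). `"merged"` sums the four
#' directional matrices.
#'
#' @inheritParams compute_glcm
#' @return Ng x R_max count matrix (R_max = max image dimension).
#' @export
compute_glrlm <- function(d, direction = "merged") {
  stopifnot(inherits(d, "discretized_image"))
  A <- d$levels; Ng <- d$n_levels
  r_max <- max(dim(A))
  dirs <- if (identical(direction, "merged")) c("0", "45", "90", "135") else
    as.character(direction)
  Reduce(`+`, lapply(dirs, function(dd)
    glrlm_one_direction(A, Ng, dd, r_max)))
}

# per-pixel neighbor aggregates over the 8-neighborhood (Chebyshev radius
# 1), respecting the mask: returns the sum of neighbor levels, the number
# of in-mask neighbors, and the number of "dependent" neighbors with
# |level - center| <= alpha.
neighbor_counts <- function(d, alpha = 0) {
  A <- d$levels; msk <- d$mask
  H <- nrow(A); W <- ncol(A)
  padL <- matrix(0, H + 2L, W + 2L); padM <- matrix(0, H + 2L, W + 2L)
  padL[2:(H + 1L), 2:(W + 1L)] <- A * msk
  padM[2:(H + 1L), 2:(W + 1L)] <- msk
  nsum <- matrix(0, H, W); ncnt <- matrix(0, H, W); ndep <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rs <- (2L + dr):(H + 1L + dr); cs <- (2L + dc):(W + 1L + dc)
    nl <- padL[rs, cs]; nm <- padM[rs, cs]
    nsum <- nsum + nl
    ncnt <- ncnt + nm
    ndep <- ndep + (abs(nl - A) <= alpha) * nm
  }
  list(nsum = nsum, ncnt = ncnt, ndep = ndep)
}

#' Neighboring gray level dependence matrix (NGLDM)
#'
#' For each in-mask pixel of level i the dependence count is
#' `j = 1 + #` in-mask neighbors (Chebyshev radius 1) whose level differs
#' from i by at most `alpha`.
#'
#' @param d a [discretize()]d image.
#' @param alpha coarseness tolerance (default 0: equal levels only).
#' @return Ng x 9 count matrix `s(i, j)`; dependence counts sum to the
#'   in-mask pixel count.
#' @export
compute_ngldm <- function(d, alpha = 0, nb = NULL) {
  stopifnot(inherits(d, "discretized_image"), alpha >= 0)
  if (is.null(nb)) nb <- neighbor_counts(d, alpha)
  msk <- d$mask
  i <- d$levels[msk]
  j <- 1L + nb$ndep[msk]
  d_max <- 9L
  matrix(tabulate(i + d$n_levels * (as.integer(j) - 1L),
                  nbins = d$n_levels * d_max), d$n_levels, d_max)
}

#' Neighborhood gray tone difference matrix (NGTDM)
#'
#' For each gray level i present in the mask: `n_i` = number of in-mask
#' pixels of level i having at least one in-mask neighbor, `p_i` their
#' fraction, and `s_i` the summed absolute difference between i and the
#' mean level of the pixel's in-mask neighbors.
#'
#' @param d a [discretize()]d image.
#' @return list with `n`, `p`, `s` (length-Ng vectors) and `n_valid`.
#' @export
compute_ngtdm <- function(d, nb = NULL) {
  stopifnot(inherits(d, "discretized_image"))
  if (is.null(nb)) nb <- neighbor_counts(d, 0)
  valid <- d$mask & nb$ncnt > 0
  i <- d$levels[valid]
  nbar <- nb$nsum[valid] / nb$ncnt[valid]
  Ng <- d$n_levels
  n_i <- tabulate(i, nbins = Ng)
  s_i <- numeric(Ng)
  contrib <- abs(i - nbar)
  agg <- rowsum(contrib, group = i)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  nvc <- sum(n_i)
  list(n = n_i, p = if (nvc > 0) n_i / nvc else n_i, s = s_i, n_valid = nvc)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find pass.
label_zones8 <- function(B) {
  lab <- EBImage::bwlabel(B)
  lab <- matrix(as.integer(lab), nrow(B), ncol(B))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  H <- nrow(B); W <- ncol(B)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # \ diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # / diagonal
  k1 <- a1 > 0L & b1 > 0L & a1 != b1
  k2 <- a2 > 0L & b2 > 0L & a2 != b2
  key <- unique(c(a1[k1] + (nlab + 1) * b1[k1],
                  a2[k2] + (nlab + 1) * b2[k2]))
  if (length(key) == 0L) return(lab)
  pairs <- cbind(as.integer(key %% (nlab + 1)),
                 as.integer(key %/% (nlab + 1)))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

# City-block distance transform of a mask (distance to the nearest
# non-mask pixel, with outside-the-image counting as background, so border
# pixels get distance 1).  Separable L1 min-convolution; each 1D pass is
# vectorized with the cummin trick  d_j = j + min(0, cummin(v_k - k)).
dist_map_cityblock <- function(mask) {
  pass1d <- function(v) {
    n <- length(v); idx <- seq_len(n)
    L <- idx + cummin(c(0, v - idx))[-1]
    w <- rev(v)
    R <- rev(idx + cummin(c(0, w - idx))[-1])
    pmin(L, R)
  }
  g <- matrix(ifelse(mask, Inf, 0), nrow(mask), ncol(mask))
  d1 <- apply(g, 2, pass1d)
  t(apply(d1, 1, pass1d))
}

#' Gray level size zone and distance zone matrices (GLSZM / GLDZM)
#'
#' Zones are 8-connected components of equal gray level within the mask.
#' The GLSZM counts zones by (level, size); the GLDZM counts zones by
#' (level, distance), where a zone's distance is the minimum city-block
#' distance of its pixels to the mask edge (border pixels have distance 1).
#' Both are returned in triplet form (`i` = level, `j` = size or distance,
#' `n` = zone count) for compactness.
#'
#' @param d a [discretize()]d image.
#' @return list with elements `szm` and `dzm`, each a data.frame
#'   `(i, j, n)`, plus `n_levels`.
#' @export
compute_zone_matrices <- function(d) {
  stopifnot(inherits(d, "discretized_image"))
  dmap <- dist_map_cityblock(d$mask)
  li <- integer(0); lsz <- integer(0); ldi <- numeric(0)
  for (lev in seq_len(d$n_levels)) {
    B <- d$levels == lev
    if (!any(B)) next
    lab <- label_zones8(B)
    inz <- lab > 0L
    z <- lab[inz]
    sizes <- tabulate(z)
    dv <- dmap[inz]
    o <- order(z, dv)
    mind <- dv[o][!duplicated(z[o])]   # per-zone minimum distance
    li <- c(li, rep(lev, length(sizes)))
    lsz <- c(lsz, sizes)
    ldi <- c(ldi, mind)
  }
  collapse <- function(i, j) {
    key <- paste(i, j)
    u <- !duplicated(key)
    n <- as.vector(table(factor(key, levels = key[u])))
    out <- data.frame(i = i[u], j = j[u], n = n)
    out[order(out$i, out$j), , drop = FALSE]
  }
  list(szm = collapse(li, lsz), dzm = collapse(li, ldi),
       n_levels = d$n_levels)
}
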