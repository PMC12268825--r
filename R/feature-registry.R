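#' Radiomic feature registry
#'
#' Defines the 152-feature-per-channel roster and the extraction
#' parameters: fixed-bin-number discretization level count, local-peak
#' radius and NGLDM coarseness tolerance. The roster covers local
#' intensity (2), intensity-based statistics (18), intensity histogram
#' (23), GLCM merged over the four 2D directions (25), GLRLM (16),
#' GLSZM (16), GLDZM (16), NGTDM (5), NGLDM (17) and 2D mask morphology
#' (14) features, all with IBSI definitions.
#'
#' @param n_levels gray levels for discretization (default 32).
#' @param peak_radius_px local-intensity-peak disc radius (default 5 px).
#' @param ngldm_alpha NGLDM dependence tolerance (default 0).
#' @return list of class `feature_registry` with a `feature_names`
#'   vector of length 152.
#' @examples
#' length(default_feature_registry()$feature_names)
#' @export
default_feature_registry <- function(n_levels = 32L, peak_radius_px = 5,
                                     ngldm_alpha = 0) {
  nm <- c(
    paste0("loc.", c("peak.local", "peak.global")),
    paste0("stat.", c("mean", "var", "skew", "kurt", "median", "min", "p10",
                      "p90", "max", "iqr", "range", "mad", "madr", "medad",
                      "cov", "qcod", "energy", "rms")),
    paste0("ih.", c("mean", "var", "skew", "kurt", "median", "min", "p10",
                    "p90", "max", "mode", "iqr", "range", "mad", "madr",
                    "medad", "cov", "qcod", "entropy", "uniformity",
                    "max.grad", "max.grad.gl", "min.grad", "min.grad.gl")),
    paste0("cm.", c("joint.max", "joint.avg", "joint.var", "joint.entr",
                    "diff.avg", "diff.var", "diff.entr", "sum.avg",
                    "sum.var", "sum.entr", "energy", "contrast",
                    "dissimilarity", "inv.diff", "inv.diff.norm",
                    "inv.diff.mom", "inv.diff.mom.norm", "inv.var", "corr",
                    "auto.corr", "clust.tend", "clust.shade", "clust.prom",
                    "info.corr.1", "info.corr.2")),
    paste0("rlm.", c("sre", "lre", "lgre", "hgre", "srlge", "srhge",
                     "lrlge", "lrhge", "glnu", "glnu.norm", "rlnu",
                     "rlnu.norm", "r.perc", "gl.var", "rl.var", "rl.entr")),
    paste0("szm.", c("sze", "lze", "lgze", "hgze", "szlge", "szhge",
                     "lzlge", "lzhge", "glnu", "glnu.norm", "zsnu",
                     "zsnu.norm", "z.perc", "gl.var", "zs.var", "zs.entr")),
    paste0("dzm.", c("sde", "lde", "lgze", "hgze", "sdlge", "sdhge",
                     "ldlge", "ldhge", "glnu", "glnu.norm", "zdnu",
                     "zdnu.norm", "z.perc", "gl.var", "zd.var", "zd.entr")),
    paste0("ngt.", c("coarseness", "contrast", "busyness", "complexity",
                     "strength")),
    paste0("ngl.", c("lde", "hde", "lgce", "hgce", "ldlge", "ldhge",
                     "hdlge", "hdhge", "glnu", "glnu.norm", "dcnu",
                     "dcnu.norm", "dc.perc", "gl.var", "dc.var", "dc.entr",
                     "dc.energy")),
    paste0("morph.", c("area", "perimeter", "pa.ratio", "circularity",
                       "compactness", "equiv.diam", "major.axis",
                       "minor.axis", "eccentricity", "elongation",
                       "extent", "solidity", "com.shift", "n.components")))
  stopifnot(length(nm) == 152L, !anyDuplicated(nm))
  structure(list(version = "1.0", n_levels = as.integer(n_levels),
                 peak_radius_px = peak_radius_px,
                 ngldm_alpha = ngldm_alpha, feature_names = nm),
            class = "feature_registry")
}

#' Extract the full registry feature vector for one channel
#'
#' @param img numeric channel matrix.
#' @param mask `roi_mask` or logical matrix (non-empty).
#' @param registry a [default_feature_registry()].
#' @return named numeric vector of 152 finite features.
#' @export
extract_channel_features <- function(img, mask,
                                     registry = default_feature_registry()) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  d <- discretize(img, mask, registry$n_levels)
  nv <- sum(mask)
  zones <- compute_zone_matrices(d)
  nb <- neighbor_counts(d, registry$ngldm_alpha)
  pfx <- function(v, p) setNames(v, paste0(p, names(v)))
  out <- c(
    setNames(c(feature_local_intensity_peak(img, mask,
                                            registry$peak_radius_px),
               feature_global_intensity_peak(img, mask,
                                             registry$peak_radius_px)),
             c("loc.peak.local", "loc.peak.global")),
    pfx(intensity_statistics(img, mask), "stat."),
    pfx(intensity_histogram_features(d), "ih."),
    pfx(glcm_features(compute_glcm(d)), "cm."),
    pfx(glrlm_features(compute_glrlm(d), nv), "rlm."),
    pfx(glszm_features(zones, nv), "szm."),
    pfx(gldzm_features(zones, nv), "dzm."),
    pfx(ngtdm_features(compute_ngtdm(d, nb = nb)), "ngt."),
    pfx(ngldm_features(compute_ngldm(d, registry$ngldm_alpha, nb = nb), nv),
        "ngl."),
    pfx(morphology_features(img, mask), "morph."))
  out <- out[registry$feature_names]
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  out
}

#' Extract both channels' features from a preprocessed plane
#'
#' Computes the registry's 152 features on the SHG and TPEF channels over
#' a shared mask (the OR-combined mask by default), yielding 304 values.
#'
#' @param pre a plane from [preprocess_plane()], or an `mpm_plane` (which
#'   is then preprocessed with defaults).
#' @param mask optional `roi_mask` overriding the plane's mask.
#' @param registry a [default_feature_registry()].
#' @return named numeric vector of length 304 with `SHG__` and `TPEF__`
#'   prefixes.
#' @export
extract_all <- function(pre, mask = NULL,
                        registry = default_feature_registry()) {
  if (inherits(pre, "mpm_plane")) pre <- preprocess_plane(pre)
  m <- mask %||% pre$mask
  shg <- extract_channel_features(pre$shg, m, registry)
  tpef <- extract_channel_features(pre$tpef, m, registry)
  c(setNames(shg, paste0("SHG__", names(shg))),
    setNames(tpef, paste0("TPEF__", names(tpef))))
}

#' Build the per-plane feature table for a cohort
#'
#' Preprocesses every plane, extracts the 304 features and assembles the
#' feature table (one row per plane; metadata columns `plane_id`,
#' `roi_id`, `tissue_class`, `binary_label` followed by the 304 feature
#' columns).
#'
#' @param cohort result of [generate_mpm_cohort()] (or `read_mpm_cohort()`).
#' @param cfg a [preprocess_config()].
#' @param registry a [default_feature_registry()].
#' @param use_mask `"or"` (default) for the OR-combined mask, `"shg"` or
#'   `"tpef"` for a per-channel mask.
#' @return data.frame of class `feature_table`.
#' @export
build_feature_table <- function(cohort, cfg = preprocess_config(),
                                registry = default_feature_registry(),
                                use_mask = c("or", "shg", "tpef")) {
  use_mask <- match.arg(use_mask)
  lab <- cohort$labels
  rows <- vector("list", length(cohort$planes))
  for (i in seq_along(cohort$planes)) {
    pre <- preprocess_plane(cohort$planes[[i]], cfg)
    m <- switch(use_mask, or = pre$mask, shg = pre$mask_shg,
                tpef = pre$mask_tpef)
    rows[[i]] <- extract_all(pre, mask = m, registry = registry)
  }
  feat <- do.call(rbind, rows)
  out <- cbind(lab[, c("plane_id", "roi_id", "tissue_class",
                       "binary_label")],
               as.data.frame(feat))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature / metadata column helpers for a feature table
#' @param table a `feature_table`.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table)
  setdiff(names(table), c("plane_id", "roi_id", "depth_index",
                          "tissue_class", "binary_label"))
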