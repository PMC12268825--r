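#' Default per-class fiber rendering parameters
#'
#' One row per tissue class, controlling the synthetic MPM generator. The
#' parameters encode the qualitative histology of infarct maturation:
#' healthy myocardium shows only a few thin, aligned collagen fibers in SHG
#' and bright, aligned cardiomyocyte laminae in TPEF; necrotic tissue shows
#' long curled fibers; granulated tissue thick intertwined fibrils; and
#' fibrotic scar a dense collagen mesh with strongly reduced TPEF.
#'
#' Columns:
#' \describe{
#'   \item{fiber_count_shg, fiber_count_tpef}{number of rendered fibers per
#'     channel (SHG density ordering healthy < necrotic < granulated <=
#'     fibrotic).}
#'   \item{orientation_concentration}{von-Mises-like concentration of fiber
#'     orientations; high values give parallel laminae, low values a random
#'     mesh.}
#'   \item{curliness}{standard deviation (radians) of the per-step turning
#'     angle of the fiber random walk.}
#'   \item{fiber_width_px}{rendered fiber width (pixels).}
#'   \item{shg_intensity_scale, tpef_intensity_scale}{channel intensity
#'     scales (TPEF ordering healthy > granulated > fibrotic).}
#'   \item{noise_sd}{additive Gaussian noise level.}
#'   \item{psf_sigma_px}{Gaussian blur applied after noise, emulating the
#'     optical point-spread function.}
#' }
#'
#' @return data.frame with row names `healthy`, `necrotic`, `granulated`,
#'   `fibrotic`.
#' @examples
#' default_fiber_params()
#' @export
default_fiber_params <- function() {
  p <- data.frame(
    row.names                 = tissue_classes(),
    fiber_count_shg           = c(8L,  30L,  60L,  90L),
    fiber_count_tpef          = c(30L, 20L,  12L,   8L),
    orientation_concentration = c(8,    2,   0.5,  0.3),
    curliness                 = c(0.05, 0.25, 0.35, 0.40),
    fiber_width_px            = c(1.5,  1.5,  2.5,  2.5),
    shg_intensity_scale       = c(0.30, 0.60, 0.80, 1.00),
    tpef_intensity_scale      = c(1.00, 0.70, 0.45, 0.25),
    noise_sd                  = c(0.02, 0.02, 0.02, 0.02),
    psf_sigma_px              = c(1.2,  1.2,  1.2,  1.2)
  )
  validate_fiber_params(p)
  p
}

validate_fiber_params <- function(p) {
  need <- c("fiber_count_shg", "fiber_count_tpef", "orientation_concentration",
            "curliness", "fiber_width_px", "shg_intensity_scale",
            "tpef_intensity_scale", "noise_sd", "psf_sigma_px")
  if (!all(need %in% names(p)))
    stop("fiber parameter table lacks columns: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  if (!all(tissue_classes() %in% rownames(p)))
    stop("fiber parameter table needs one row per tissue class")
  pos <- c("fiber_count_shg", "fiber_count_tpef", "fiber_width_px",
           "shg_intensity_scale", "tpef_intensity_scale", "noise_sd",
           "psf_sigma_px")
  for (col in pos)
    if (any(p[[col]] <= 0)) stop("parameter '", col, "' must be positive")
  dens <- p[tissue_classes(), "fiber_count_shg"]
  if (!(dens[1] < dens[2] && dens[2] < dens[3] && dens[3] <= dens[4]))
    stop("SHG fiber density must be ordered healthy < necrotic < granulated <= fibrotic")
  tp <- p[c("healthy", "granulated", "fibrotic"), "tpef_intensity_scale"]
  if (!(tp[1] > tp[2] && tp[2] > tp[3]))
    stop("TPEF intensity must be ordered healthy > granulated > fibrotic")
  invisible(TRUE)
}

# von-Mises-like orientation sample: wrapped-normal approximation with
# sd = 1/sqrt(kappa); near-zero concentration falls back to uniform.
rvonmises_like <- function(n, mu, kappa) {
  if (kappa < 1e-3) return(runif(n, -pi, pi))
  (mu + rnorm(n, 0, 1 / sqrt(kappa) + 1e-12) + pi) %% (2 * pi) - pi
}

# Rasterize bounded random-walk fibers onto an H x W canvas.  Fibers are
# drawn as 1-px polylines (unit steps), then widened by a Gaussian blur of
# sigma = width/2 so that anti-aliased width emerges without per-pixel
# stamping.
render_fibers <- function(H, W, n_fibers, mu, kappa, curl, width_px) {
  canvas <- matrix(0, H, W)
  for (f in seq_len(n_fibers)) {
    theta0 <- rvonmises_like(1L, mu, kappa)
    len <- max(16L, round(runif(1, 0.3, 0.9) * min(H, W)))
    theta <- theta0 + cumsum(rnorm(len, 0, curl))
    x <- runif(1, 1, W) + c(0, cumsum(cos(theta)))
    y <- runif(1, 1, H) + c(0, cumsum(sin(theta)))
    ix <- round(x); iy <- round(y)
    ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
    if (!any(ok)) next
    amp <- runif(1, 0.7, 1.3)
    idx <- cbind(iy[ok], ix[ok])
    canvas[idx] <- canvas[idx] + amp
  }
  if (any(canvas > 0)) {
    sig <- max(width_px / 2, 0.35)
    canvas <- EBImage::gblur(canvas, sigma = sig)
    canvas[canvas < 0] <- 0
  }
  canvas
}

#' Generate one synthetic two-channel MPM plane
#'
#' Renders a seeded, deterministic SHG/TPEF image pair for a given tissue
#' class. The SHG channel draws collagen-like fibers as smoothed random-walk
#' polylines whose density, alignment and curliness follow the class
#' parameters; the TPEF channel draws broader myocyte laminae sharing the
#' same dominant orientation, at the class intensity. Additive Gaussian
#' noise is applied, then a Gaussian blur emulating the optical PSF.
#'
#' @param cls tissue class (`"healthy"`/`"muscle"`, `"necrotic"`,
#'   `"granulated"` or `"fibrotic"`).
#' @param params per-class parameter table, see [default_fiber_params()].
#' @param shape integer vector `c(H, W)`, at least 64 x 64.
#' @param seed integer seed; identical inputs give bitwise-identical planes.
#' @param roi_id,depth_index metadata carried on the plane.
#' @return an object of class `mpm_plane`: list with `shg` and `tpef`
#'   matrices (same shape, finite, non-negative), `tissue_class`,
#'   `binary_label`, `roi_id`, `depth_index`, `seed`.
#' @examples
#' pl <- generate_mpm_plane("fibrotic", shape = c(64, 64), seed = 1)
#' range(pl$shg)
#' @export
generate_mpm_plane <- function(cls, params = default_fiber_params(),
                               shape = c(256, 256), seed = 1L,
                               roi_id = "ROI1", depth_index = 0L) {
  cls <- assert_tissue_class(cls)
  validate_fiber_params(params)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    stop("'shape' must be two integers, each >= 64")
  p <- params[cls, ]
  with_seed(seed, {
    H <- shape[1]; W <- shape[2]
    mu <- runif(1, -pi, pi)  # dominant tissue orientation of this plane
    shg <- render_fibers(H, W, p$fiber_count_shg, mu,
                         p$orientation_concentration, p$curliness,
                         p$fiber_width_px) * p$shg_intensity_scale
    tpef <- render_fibers(H, W, p$fiber_count_tpef, mu,
                          p$orientation_concentration, p$curliness * 0.8,
                          p$fiber_width_px * 3) * p$tpef_intensity_scale
    tpef <- tpef + 0.05 * p$tpef_intensity_scale  # diffuse autofluorescence
    shg <- shg + matrix(rnorm(H * W, 0, p$noise_sd), H, W)
    tpef <- tpef + matrix(rnorm(H * W, 0, p$noise_sd), H, W)
    shg <- EBImage::gblur(shg, sigma = p$psf_sigma_px)
    tpef <- EBImage::gblur(tpef, sigma = p$psf_sigma_px)
    shg[shg < 0] <- 0
    tpef[tpef < 0] <- 0
    structure(list(shg = shg, tpef = tpef, tissue_class = cls,
                   binary_label = binary_label(cls), roi_id = roi_id,
                   depth_index = as.integer(depth_index),
                   seed = as.integer(seed)),
              class = "mpm_plane")
  })
}

#' @export
print.mpm_plane <- function(x, ...) {
  cat(sprintf("<mpm_plane %dx%d  class=%s (%s)  roi=%s depth=%d seed=%d>\n",
              nrow(x$shg), ncol(x$shg), x$tissue_class, x$binary_label,
              x$roi_id, x$depth_index, x$seed))
  invisible(x)
}

#' Cohort specifications for synthetic MPM data
#'
#' `mpm_cohort_spec()` builds a cohort specification; the two canned
#' defaults reproduce the study design used throughout the package: a
#' training/validation cohort of 56 healthy and 128 pathologic planes
#' (43 necrotic, 43 granulated, 42 fibrotic) over 3 ROIs, and a test
#' cohort of 378 planes over 6 ROIs.
#'
#' @param planes_per_class named integer vector over the four tissue
#'   classes.
#' @param n_rois number of regions of interest; planes are assigned
#'   round-robin.
#' @param shape image shape `c(H, W)`.
#' @param seed integer root seed.
#' @return list of class `mpm_cohort_spec`.
#' @examples
#' default_training_spec()
#' @export
mpm_cohort_spec <- function(planes_per_class, n_rois = 3L,
                            shape = c(256, 256), seed = 1L) {
  planes_per_class <- planes_per_class[planes_per_class > 0]
  if (length(planes_per_class) == 0L || sum(planes_per_class) < 1L)
    stop("at least one plane must be requested")
  bad <- setdiff(names(planes_per_class), tissue_classes())
  if (length(bad)) stop("unknown tissue class: ", paste(bad, collapse = ", "))
  structure(list(planes_per_class = planes_per_class,
                 n_rois = as.integer(n_rois), shape = as.integer(shape),
                 seed = as.integer(seed)),
            class = "mpm_cohort_spec")
}

#' @rdname mpm_cohort_spec
#' @export
default_training_spec <- function(shape = c(256, 256), seed = 101L)
  mpm_cohort_spec(c(healthy = 56L, necrotic = 43L, granulated = 43L,
                    fibrotic = 42L),
                  n_rois = 3L, shape = shape, seed = seed)

#' @rdname mpm_cohort_spec
#' @export
default_test_spec <- function(shape = c(256, 256), seed = 202L)
  mpm_cohort_spec(c(healthy = 94L, necrotic = 95L, granulated = 95L,
                    fibrotic = 94L),
                  n_rois = 6L, shape = shape, seed = seed)

#' Generate a synthetic MPM cohort
#'
#' Generates all planes of a cohort specification with per-plane seeds
#' derived from the cohort seed, assigns planes round-robin to ROIs, and
#' returns the planes plus a label table.
#'
#' @param spec an [mpm_cohort_spec()].
#' @param params per-class fiber parameters, see [default_fiber_params()].
#' @return list with `planes` (list of `mpm_plane`) and `labels`
#'   (data.frame with columns `plane_id`, `roi_id`, `depth_index`,
#'   `tissue_class`, `binary_label`), one row per plane.
#' @examples
#' co <- generate_mpm_cohort(mpm_cohort_spec(c(healthy = 2, fibrotic = 2),
#'                                           shape = c(64, 64)))
#' co$labels
#' @export
generate_mpm_cohort <- function(spec, params = default_fiber_params()) {
  stopifnot(inherits(spec, "mpm_cohort_spec"))
  classes <- rep(names(spec$planes_per_class), spec$planes_per_class)
  n <- length(classes)
  roi <- sprintf("ROI%d", ((seq_len(n) - 1L) %% spec$n_rois) + 1L)
  depth <- integer(n)
  for (r in unique(roi)) depth[roi == r] <- seq_len(sum(roi == r)) - 1L
  planes <- vector("list", n)
  for (i in seq_len(n)) {
    planes[[i]] <- generate_mpm_plane(
      classes[i], params = params, shape = spec$shape,
      seed = derive_seed(spec$seed, 1L, i), roi_id = roi[i],
      depth_index = depth[i])
  }
  labels <- data.frame(
    plane_id = sprintf("plane%04d", seq_len(n)), roi_id = roi,
    depth_index = depth, tissue_class = classes,
    binary_label = binary_label(classes), stringsAsFactors = FALSE)
  list(planes = planes, labels = labels)
}

#' Write an MPM cohort to disk
#'
#' Writes each plane as a two-channel TIFF (channel 1 = SHG, channel 2 =
#' TPEF; intensities scaled jointly into \[0, 1\] with the scale recorded in
#' the label table) and the label table as CSV.
#'
#' @param cohort result of [generate_mpm_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the label table with a `path` and
#'   `intensity_scale` column added.
#' @export
write_mpm_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- cohort$labels
  lab$path <- file.path(dir, paste0(lab$plane_id, ".tiff"))
  lab$intensity_scale <- NA_real_
  for (i in seq_along(cohort$planes)) {
    pl <- cohort$planes[[i]]
    sc <- max(pl$shg, pl$tpef, 1e-12)
    tiff::writeTIFF(list(pl$shg / sc, pl$tpef / sc), lab$path[i],
                    bits.per.sample = 16L)
    lab$intensity_scale[i] <- sc
  }
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(lab)
}

#' Read an MPM cohort written by [write_mpm_cohort()]
#'
#' @param dir directory containing `labels.csv` and the plane TIFFs.
#' @return list with `planes` and `labels` as in [generate_mpm_cohort()].
#' @export
read_mpm_cohort <- function(dir) {
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  planes <- lapply(seq_len(nrow(lab)), function(i) {
    arr <- tiff::readTIFF(lab$path[i], all = TRUE)
    sc <- lab$intensity_scale[i]
    structure(list(shg = arr[[1]] * sc, tpef = arr[[2]] * sc,
                   tissue_class = lab$tissue_class[i],
                   binary_label = lab$binary_label[i],
                   roi_id = lab$roi_id[i],
                   depth_index = lab$depth_index[i], seed = NA_integer_),
              class = "mpm_plane")
  })
  list(planes = planes, labels = lab)
}
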