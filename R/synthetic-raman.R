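#' Default Raman band model for fibrotic myocardium
#'
#' Band centers, Lorentzian widths and per-class amplitudes used by the
#' synthetic spectrum generator. The eleven bands are the
#' collagen/protein-associated modes of cardiac tissue: proline C-C
#' stretch (728), cytochrome (750), C-C/choline (869), collagen backbone
#' C-C (937), amide III (1260), CH2 twist/wag (1302), CH2/CH3 wag (1338),
#' CH2/CH3 deformation (1446), amide I (1650), and the CH-stretch modes
#' (2880, 2920 cm-1).
#'
#' Amplitudes of the collagen-associated bands increase monotonically
#' along the class order muscle, necrotic, granulated, fibrotic; the
#' CH-stretch bands decrease along that order; amide I has the largest
#' inter-class amplitude range of all bands, reflecting its link to
#' collagen fiber packing. The wavenumber axis covers the fingerprint
#' (600-1800 cm-1) and CH-stretch (2700-3100 cm-1) regions at 2 cm-1
#' spacing; the silent region between them is omitted.
#'
#' @param noise_sd Gaussian noise level added per channel.
#' @return list of class `raman_band_model` with `centers`, `widths`,
#'   `amplitudes` (band x class matrix), `baseline_scale`, `noise_sd`,
#'   `axis`.
#' @examples
#' m <- default_band_model()
#' m$centers
#' @export
default_band_model <- function(noise_sd = 0.01) {
  centers <- c(728, 750, 869, 937, 1260, 1302, 1338, 1446, 1650, 2880, 2920)
  widths <- c(rep(10, 9), 22, 22)  # Lorentzian HWHM, cm-1
  # Collagen-band amplitudes are non-decreasing along infarct maturation,
  # CH-stretch bands non-increasing, but the bands mature at different
  # stages (amide III early, backbone C-C late), and the cytochrome band
  # tracks mitochondrial content rather than collagen.  The resulting
  # class signatures are multi-dimensional, not a single fibrosis axis.
  A <- rbind(
    `728`  = c(0.08, 0.20, 0.22, 0.30),
    `750`  = c(0.30, 0.06, 0.18, 0.10),
    `869`  = c(0.08, 0.10, 0.28, 0.34),
    `937`  = c(0.08, 0.10, 0.28, 0.34),
    `1260` = c(0.12, 0.35, 0.38, 0.55),
    `1302` = c(0.12, 0.30, 0.32, 0.48),
    `1338` = c(0.12, 0.14, 0.35, 0.48),
    `1446` = c(0.35, 0.55, 0.76, 1.00),
    `1650` = c(0.25, 0.55, 0.88, 1.25),
    `2880` = c(0.85, 0.80, 0.50, 0.40),
    `2920` = c(1.05, 0.85, 0.80, 0.50))
  colnames(A) <- raman_classes()
  axis <- c(seq(600, 1800, by = 2), seq(2700, 3100, by = 2))
  m <- structure(list(centers = centers, widths = widths, amplitudes = A,
                      baseline_scale = 0.05, amplitude_jitter_sd = 0.10,
                      noise_sd = noise_sd, axis = axis),
                 class = "raman_band_model")
  validate_band_model(m)
  m
}

validate_band_model <- function(m) {
  stopifnot(length(m$centers) == length(m$widths),
            nrow(m$amplitudes) == length(m$centers),
            ncol(m$amplitudes) == 4L, all(m$amplitudes >= 0),
            all(m$widths > 0), m$noise_sd >= 0)
  if (any(diff(m$axis) <= 0)) stop("wavenumber axis must be strictly increasing")
  coll <- as.character(c(728, 869, 937, 1260, 1302, 1338, 1446, 1650))
  for (b in intersect(coll, rownames(m$amplitudes)))
    if (any(diff(m$amplitudes[b, ]) < 0))
      stop("collagen band ", b, " amplitudes must be non-decreasing ",
           "muscle -> fibrotic")
  for (b in intersect(c("2880", "2920"), rownames(m$amplitudes)))
    if (any(diff(m$amplitudes[b, ]) > 0))
      stop("CH band ", b, " amplitudes must be non-increasing muscle -> fibrotic")
  rng <- apply(m$amplitudes, 1, function(a) diff(range(a)))
  if (rownames(m$amplitudes)[which.max(rng)] != "1650")
    stop("amide I (1650) must have the largest inter-class amplitude range")
  invisible(TRUE)
}

lorentzian <- function(nu, center, hwhm) hwhm^2 / ((nu - center)^2 + hwhm^2)

#' Generate a synthetic Raman spectrum set
#'
#' Each spectrum is a sum of Lorentzian bands with class-dependent
#' amplitudes, plus a low-order polynomial baseline with small random
#' coefficients (emulating autofluorescence background) and Gaussian
#' noise. Seeded and deterministic.
#'
#' @param n_per_class spectra per class; either a single integer or a named
#'   vector over [raman_classes()].
#' @param band_model a [default_band_model()]-style model.
#' @param seed integer seed.
#' @return list of class `raman_set`: `axis` (wavenumbers), `X`
#'   (spectra x channels intensity matrix), `labels` (factor with the
#'   canonical class order), `preprocessing` (character vector of applied
#'   steps, empty here).
#' @examples
#' rs <- generate_raman_set(5, seed = 1)
#' dim(rs$X)
#' @export
generate_raman_set <- function(n_per_class = 40L,
                               band_model = default_band_model(),
                               seed = 1L) {
  validate_band_model(band_model)
  classes <- raman_classes()
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- setNames(rep(as.integer(n_per_class), 4L), classes)
  if (!all(names(n_per_class) %in% classes) || length(n_per_class) == 0L)
    stop("'n_per_class' must be named over the canonical classes")
  if (any(n_per_class < 1L)) stop("'n_per_class' must be >= 1 per class")
  axis <- band_model$axis
  nb <- length(band_model$centers)
  # band x channel design matrix of unit Lorentzians
  L <- vapply(seq_len(nb), function(b)
    lorentzian(axis, band_model$centers[b], band_model$widths[b]),
    numeric(length(axis)))
  labels <- factor(rep(names(n_per_class), n_per_class), levels = classes)
  n <- length(labels)
  with_seed(seed, {
    u <- (axis - min(axis)) / diff(range(axis))
    X <- matrix(0, n, length(axis))
    for (i in seq_len(n)) {
      amp <- band_model$amplitudes[, as.character(labels[i])]
      jit <- band_model$amplitude_jitter_sd %||% 0.10
      if (jit > 0) amp <- amp * exp(rnorm(nb, 0, jit))
      sig <- as.vector(L %*% amp)
      cf <- rnorm(4, 0, band_model$baseline_scale)
      base <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3 + 2 * band_model$baseline_scale
      X[i, ] <- sig + base + rnorm(length(axis), 0, band_model$noise_sd)
    }
    structure(list(axis = axis, X = X, labels = labels,
                   preprocessing = character(0)),
              class = "raman_set")
  })
}

#' @export
print.raman_set <- function(x, ...) {
  cat(sprintf("<raman_set  %d spectra x %d channels  [%g-%g cm-1]>\n",
              nrow(x$X), ncol(x$X), min(x$axis), max(x$axis)))
  print(table(x$labels))
  invisible(x)
}

#' Write / read a Raman spectrum set as CSV
#'
#' The spectra file has `wavenumber_cm1` as first column and one column
#' per spectrum; the companion labels file has `spectrum_id` and
#' `tissue_class`.
#'
#' @param set a `raman_set`.
#' @param dir output directory.
#' @return invisibly (write) or a `raman_set` (read).
#' @export
write_raman_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("spec%04d", seq_len(nrow(set$X)))
  sp <- data.frame(wavenumber_cm1 = set$axis, t(set$X))
  names(sp)[-1] <- ids
  write.csv(sp, file.path(dir, "spectra.csv"), row.names = FALSE)
  write.csv(data.frame(spectrum_id = ids,
                       tissue_class = as.character(set$labels)),
            file.path(dir, "spectra_labels.csv"), row.names = FALSE)
  invisible(set)
}

#' @rdname write_raman_set
#' @export
read_raman_set <- function(dir) {
  sp <- read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  lab <- read.csv(file.path(dir, "spectra_labels.csv"),
                  stringsAsFactors = FALSE)
  X <- t(as.matrix(sp[, -1, drop = FALSE]))
  dimnames(X) <- NULL
  structure(list(axis = sp$wavenumber_cm1, X = X,
                 labels = factor(lab$tissue_class, levels = raman_classes()),
                 preprocessing = character(0)),
            class = "raman_set")
}
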