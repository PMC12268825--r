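#' Tissue class vocabulary
#'
#' Histopathologic tissue classes used throughout the package. The
#' four-class order is fixed as muscle (healthy), necrotic, granulated,
#' fibrotic; the three non-muscle classes are summarised as "pathologic"
#' for the binary MPM classification task.
#'
#' @return `tissue_classes()` returns the canonical four-class character
#'   vector; `binary_label()` maps tissue classes to `"healthy"` /
#'   `"pathologic"`.
#' @examples
#' tissue_classes()
#' binary_label(c("healthy", "fibrotic"))
#' @export
tissue_classes <- function() c("healthy", "necrotic", "granulated", "fibrotic")

#' Canonical Raman class order (muscle is the healthy myocardium class)
#' @rdname tissue_classes
#' @export
raman_classes <- function() c("muscle", "necrotic", "granulated", "fibrotic")

#' @param cls character vector of tissue class labels (`"muscle"` is
#'   accepted as a synonym of `"healthy"`).
#' @rdname tissue_classes
#' @export
binary_label <- function(cls) {
  cls <- as.character(cls)
  bad <- setdiff(unique(cls), c(tissue_classes(), "muscle"))
  if (length(bad))
    stop("unknown tissue class: ", paste(bad, collapse = ", "))
  ifelse(cls %in% c("healthy", "muscle"), "healthy", "pathologic")
}

assert_tissue_class <- function(cls) {
  if (length(cls) != 1L || !cls %in% c(tissue_classes(), "muscle"))
    stop("'cls' must be one of: ",
         paste(c(tissue_classes(), "muscle"), collapse = ", "))
  if (cls == "muscle") "healthy" else cls
}
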