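#' Standardize intensities to mean zero, SD one
#'
#' Affine rescaling of a volume so its intensity distribution has mean 0
#' and (population) standard deviation 1. A voxel sitting at mu + 2*sigma of
#' the original distribution maps exactly to 2.00, which is what makes the
#' downstream DWI hyperintensity threshold of 2.00 meaningful.
#'
#' @param x numeric array (any shape).
#' @return Standardized array of the same shape, with the original `mean`
#'   and `sd` attached as attributes `"mu"` and `"sigma"` (provenance).
#' @export
standardize <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # population SD
  if (!is.finite(sigma) || sigma < 1e-12) {
    stopf("degenerate volume: intensity SD is zero, cannot standardize")
  }
  out <- (x - mu) / sigma
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Standardize all sequences of a multiparametric volume
#'
#' Standardization is applied per sequence, per subject (the scope of "the
#' intensity distribution" is configurable in principle, but per-sequence is
#' the default and the only mode used by the pipeline).
#'
#' @param volume an [mp_volume].
#' @return An [mp_volume] whose sequences each have mean 0 and SD 1; the
#'   per-sequence `mu`/`sigma` provenance is kept in the
#'   `"standardization"` attribute and `"standardized"` is set to TRUE.
#' @export
standardize_volume <- function(volume) {
  stopifnot(inherits(volume, "mp_volume"))
  prov <- list()
  for (s in names(volume$sequences)) {
    z <- standardize(volume$sequences[[s]])
    prov[[s]] <- c(mu = attr(z, "mu"), sigma = attr(z, "sigma"))
    attributes(z) <- list(dim = dim(z))
    volume$sequences[[s]] <- z
  }
  attr(volume, "standardization") <- prov
  attr(volume, "standardized") <- TRUE
  volume
}

is_standardized <- function(volume) isTRUE(attr(volume, "standardized"))
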