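# unit-sum 1D Gaussian (separable-filter factor)
gaussKernel1d <- function(sigmaPx, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigmaPx))
  g <- exp(-((-radius):radius)^2 / (2 * sigmaPx^2))
  g / sum(g)
}

# render a unit-sum centered Gaussian kernel truncated at +/- 4 sigma
gaussKernelMatrix <- function(sigmaPx, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigmaPx))
  ax <- (-radius):radius
  g <- exp(-ax^2 / (2 * sigmaPx^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian model point spread function
#'
#' Renders a normalised 2D Gaussian PSF from optical parameters. The
#' in-focus width follows the Gaussian approximation of the Airy core,
#' \eqn{\sigma = 0.21\,\lambda/\mathrm{NA}}; defocus widens it as
#' \eqn{\sigma(\Delta z) = \sqrt{\sigma_0^2 + (0.5\,\mathrm{NA}\,\Delta z/n)^2}}
#' (geometric-optics blur growth, immersion index `nMedium`). The kernel is
#' truncated at \eqn{\pm 4\sigma} (odd side length) and renormalised to sum 1.
#'
#' @param wavelengthNm emission or excitation wavelength, nanometres.
#' @param na numerical aperture.
#' @param pixelSizeNm sampling pixel size, nanometres.
#' @param defocusUm axial defocus distance in micrometres (>= 0).
#' @param role `"excitation"` or `"emission"`.
#' @param sigmaNm optional explicit in-focus width, overriding the
#'   \eqn{0.21\lambda/\mathrm{NA}} default.
#' @param twoPhoton if `TRUE` the rendered profile is the square of the
#'   Gaussian (equivalently \eqn{\sigma/\sqrt 2}), modelling two-photon
#'   excitation sharpening; meaningful for the excitation PSF only.
#' @param nMedium refractive index used by the defocus model (default 1.33).
#' @return a [PsfKernel-class].
#' @examples
#' psf <- makeGaussianPsf(560, 1.1, 130, role = "emission")
#' psfSigma(psf)
#' @export
makeGaussianPsf <- function(wavelengthNm, na, pixelSizeNm, defocusUm = 0,
                            role = c("emission", "excitation"),
                            sigmaNm = NULL, twoPhoton = FALSE,
                            nMedium = 1.33) {
  role <- match.arg(role)
  stopIfNot(wavelengthNm > 0 && na > 0 && pixelSizeNm > 0,
            "physical parameters must be positive")
  stopIfNot(defocusUm >= 0, "defocusUm must be >= 0")
  if (is.null(sigmaNm)) sigmaNm <- 0.21 * wavelengthNm / na
  sigmaNm <- sqrt(sigmaNm^2 + (0.5 * na * defocusUm * 1000 / nMedium)^2)
  sigmaPx <- sigmaNm / pixelSizeNm
  if (twoPhoton) sigmaPx <- sigmaPx / sqrt(2)
  if (sigmaPx < 0.2)
    stop("PSF sigma below 0.2 px: unresolvable at this pixel size",
         call. = FALSE)
  new("PsfKernel", kernel = gaussKernelMatrix(sigmaPx), sigmaPx = sigmaPx,
      wavelengthNm = wavelengthNm, na = na, defocusUm = defocusUm,
      role = role)
}
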