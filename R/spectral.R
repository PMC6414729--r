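#' Spectral calibration (pixel to wavelength)
#'
#' A third-order polynomial mapping detector pixels to wavelength, with the
#' local bin width given by the derivative of the polynomial. The mapping
#' must be strictly monotonic over the detector range.
#'
#' @param coefficients Length-4 numeric: wavelength = c0 + c1 x + c2 x^2 +
#'   c3 x^3 with x the pixel index.
#' @param pixel_range Integer range of valid pixels (inclusive).
#' @return An object of class `pb_spectral_cal`.
#' @export
spectral_calibration <- function(coefficients, pixel_range = c(0, 511)) {
    if (length(coefficients) != 4) stop("need 4 polynomial coefficients")
    cal <- structure(list(coefficients = as.numeric(coefficients),
                          pixel_range = pixel_range),
                     class = "pb_spectral_cal")
    px <- seq(pixel_range[1], pixel_range[2], length.out = 513)
    lam <- cal_lambda(cal, px)
    if (any(diff(lam) <= 0) && any(diff(lam) >= 0) &&
        !(all(diff(lam) > 0) || all(diff(lam) < 0)))
        stop("calibration is not strictly monotonic over the detector range")
    if (!(all(diff(lam) > 0) || all(diff(lam) < 0)))
        stop("calibration is not strictly monotonic over the detector range")
    cal
}

cal_lambda <- function(cal, pixel) {
    cf <- cal$coefficients
    cf[1] + cf[2] * pixel + cf[3] * pixel^2 + cf[4] * pixel^3
}

cal_binwidth <- function(cal, pixel) {
    cf <- cal$coefficients
    abs(cf[2] + 2 * cf[3] * pixel + 3 * cf[4] * pixel^2)
}

#' Fit a spectral calibration from known line positions
#'
#' Ordinary least-squares cubic fit of wavelength against pixel for
#' calibration line samples (laser lines, dye emission peaks).
#'
#' @param pixel Pixel positions of the calibration lines.
#' @param lambda_nm Known wavelengths, nm.
#' @param pixel_range Detector pixel range.
#' @return A `pb_spectral_cal`.
#' @export
fit_spectral_calibration <- function(pixel, lambda_nm,
                                     pixel_range = c(0, 511)) {
    if (length(pixel) < 4) stop("need at least 4 calibration lines")
    fit <- lm(lambda_nm ~ pixel + I(pixel^2) + I(pixel^3))
    spectral_calibration(coef(fit), pixel_range)
}

#' Wavelength-bin-width-corrected emission spectrum
#'
#' Divides per-pixel counts by the local wavelength bin width (the derivative
#' of the pixel-to-wavelength polynomial), yielding a spectral density on the
#' calibrated wavelength grid. The integral of the density over wavelength
#' equals the total counts.
#'
#' @param counts Per-pixel counts.
#' @param cal A `pb_spectral_cal`.
#' @param pixels Pixel indices (default `0:(length(counts)-1)`).
#' @return Object of class `pb_spectrum`: `lambda_nm`, `em` (density),
#'   `bin_width_nm`, `counts`.
#' @export
calibrate_spectrum <- function(counts, cal, pixels = seq_along(counts) - 1) {
    lam <- cal_lambda(cal, pixels)
    if (!(all(diff(lam) > 0) || all(diff(lam) < 0)))
        stop("calibration is not monotonic over the supplied pixels")
    w <- cal_binwidth(cal, pixels)
    structure(list(lambda_nm = lam, em = counts / w, bin_width_nm = w,
                   counts = counts),
              class = "pb_spectrum")
}

#' Spectral center of mass
#'
#' The weighted normalized sum `sum(lambda_k Em_k) / sum(Em_k)`.
#'
#' @param em Spectral intensities, or a `pb_spectrum`.
#' @param lambda_nm Wavelength grid (ignored when `em` is a `pb_spectrum`).
#' @return Center of mass, nm.
#' @export
lambda_cm <- function(em, lambda_nm = NULL) {
    if (inherits(em, "pb_spectrum")) {
        lambda_nm <- em$lambda_nm
        em <- em$em
    }
    if (is.null(lambda_nm)) stop("wavelength grid required")
    s <- sum(em)
    if (!(s > 0)) stop("all-zero spectrum: center of mass undefined")
    sum(lambda_nm * em) / s
}
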