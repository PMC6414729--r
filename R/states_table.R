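#' Construct a photophysical state parameter set
#'
#' A `pb_state` describes one photophysical state of a trapped particle as
#' seen by the instrument: absolute brightness, fluorescence lifetime
#' components, polarization, and an emission spectrum (a Gaussian mixture in
#' wavelength).
#'
#' @param label State label (e.g. "U", "B", "Q1", "Q2", or custom).
#' @param brightness cts s^-1 uW^-1.
#' @param lifetime_components data.frame with columns `tau_ns` and
#'   `amplitude` (amplitudes must sum to 1).
#' @param fpol Fluorescence polarization in \[-1, 1\].
#' @param spectrum data.frame with columns `peak_nm`, `fwhm_nm`, `weight`
#'   (weights sum to 1): Gaussian mixture emission spectrum.
#' @return A `pb_state`.
#' @export
pb_state <- function(label, brightness, lifetime_components, fpol, spectrum) {
    if (brightness < 0) stop("brightness must be >= 0")
    if (abs(fpol) > 1) stop("|fpol| must be <= 1")
    if (abs(sum(lifetime_components$amplitude) - 1) > 1e-9)
        stop("lifetime amplitudes must sum to 1")
    if (abs(sum(spectrum$weight) - 1) > 1e-9)
        stop("spectrum weights must sum to 1")
    structure(list(label = label, brightness = brightness,
                   lifetime_components = lifetime_components,
                   fpol = fpol, spectrum = spectrum),
              class = "pb_state")
}

# Two-Gaussian emission spectrum whose analytic intensity-weighted mean
# equals lambda_cm_nm, mixing a C-PC-like band at `blue_nm` and an APC-like
# band at `red_nm`.
two_band_spectrum <- function(lambda_cm_nm, blue_nm = 650, red_nm = 680,
                              fwhm_nm = c(25, 22)) {
    p <- (red_nm - lambda_cm_nm) / (red_nm - blue_nm)
    if (p < 0 || p > 1) stop("lambda_cm outside the band span")
    data.frame(peak_nm = c(blue_nm, red_nm), fwhm_nm = fwhm_nm,
               weight = c(p, 1 - p))
}

#' Reference photophysical state table for CB-PB with and without OCP
#'
#' The four states resolved by ABEL-trap multiparameter spectroscopy of the
#' truncated CB-PB phycobilisome: unquenched (U), singly OCP-quenched (Q1),
#' doubly OCP-quenched (Q2), and detached single C-PC hexamer (B), with the
#' measured mean and standard deviation of brightness, lifetime, spectral
#' center of mass and polarization of each. Used as ground truth by the
#' synthetic generator and as the classification model.
#'
#' Each state's emission spectrum is modeled as a two-Gaussian band mixture
#' constructed so its analytic center of mass equals the measured value.
#'
#' @return A list with `states` (named list of [pb_state()]) and `model`
#'   (a `pb_state_model` suitable for [classify_groups()]).
#' @export
cbpb_reference_states <- function() {
    tab <- data.frame(
        state = c("U", "Q1", "Q2", "B"),
        Br = c(10420, 1160, 600, 1630),
        Br_sd = c(1670, 250, 140, 320),
        tau = c(1.66, 0.21, 0.09, 1.64),
        tau_sd = c(0.14, 0.03, 0.02, 0.14),
        lcm = c(669, 667, 665, 659),
        lcm_sd = c(1.4, 1.0, 0.9, 0.9),
        fpol = c(0, 0, 0, 0),
        fpol_sd = c(0.05, 0.05, 0.06, 0.05))
    states <- lapply(seq_len(nrow(tab)), function(i) {
        pb_state(label = tab$state[i],
                 brightness = tab$Br[i],
                 lifetime_components = data.frame(tau_ns = tab$tau[i], amplitude = 1),
                 fpol = tab$fpol[i],
                 spectrum = two_band_spectrum(tab$lcm[i]))
    })
    names(states) <- tab$state
    model <- structure(tab, class = c("pb_state_model", "data.frame"))
    list(states = states, model = model)
}
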