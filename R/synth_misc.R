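#' Generate a synthetic bulk TCSPC decay histogram
#'
#' Draws photon delays from a normalized exponential mixture convolved with a
#' Gaussian IRF (negative draws redrawn) and histograms them on the native
#' 4 ps TCSPC grid over the pulse window.
#'
#' @param components data.frame with columns `tau_ns`, `amplitude`
#'   (amplitudes must sum to 1).
#' @param n_photons Number of photons (> 0).
#' @param irf_fwhm_ps Gaussian IRF FWHM, ps.
#' @param seed Optional RNG seed.
#' @param window_ns TCSPC window, ns.
#' @param grid_ns Native histogram grid, ns (4 ps).
#' @return Object of class `pb_decay_histogram`: `edges_ns`, `mids_ns`,
#'   `counts`, `n_photons`.
#' @export
generate_bulk_decay <- function(components, n_photons, irf_fwhm_ps = 50,
                                seed = NULL, window_ns = 12.5,
                                grid_ns = 0.004) {
    if (n_photons <= 0) stop("n_photons must be > 0")
    if (abs(sum(components$amplitude) - 1) > 1e-9)
        stop("component amplitudes must sum to 1")
    with_seed(seed, {
        d <- sample_delays(n_photons, components, irf_fwhm_ps, window_ns)
        # TCSPC binning: a delay is recorded as the 4 ps bin it falls in
        edges <- seq(0, window_ns, by = grid_ns)
        counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                           nbins = length(edges) - 1)
        structure(list(edges_ns = edges,
                       mids_ns = (edges[-1] + edges[-length(edges)]) / 2,
                       counts = counts, n_photons = n_photons),
                  class = "pb_decay_histogram")
    })
}

#' Generate synthetic rod brightness values
#'
#' Brightness sample for dissociating C-PC rods: a Gaussian mixture over
#' 1-, 2-, and 3-hexamer species with means `(1, 2, 3) x br_1hex` and
#' proportional widths `(1, 2, 3) x sigma_1hex`.
#'
#' @param br_1hex Single-hexamer brightness, cts s^-1 uW^-1.
#' @param sigma_1hex Single-hexamer brightness standard deviation.
#' @param mixture_weights Length-3 weights over (1, 2, 3)-hexamer species
#'   (must sum to 1).
#' @param n Sample size.
#' @param seed Optional RNG seed.
#' @return Numeric vector of brightness values.
#' @export
generate_rod_brightness_sample <- function(br_1hex, sigma_1hex,
                                           mixture_weights = c(1, 1, 1) / 3,
                                           n = 3000, seed = NULL) {
    if (abs(sum(mixture_weights) - 1) > 1e-9)
        stop("mixture weights must sum to 1")
    with_seed(seed, {
        k <- sample.int(3, n, replace = TRUE, prob = mixture_weights)
        rnorm(n, mean = k * br_1hex, sd = k * sigma_1hex)
    })
}

#' Simulate OCP unbinding population time series
#'
#' Each complex starts with two independently bound OCPs (binding
#' saturation); each OCP unbinds after an exponential waiting time with rate
#' `k_off`. At time t the surviving-OCP count per complex is Binomial(2, p)
#' with p = exp(-k_off t); complexes map 2 -> Q2, 1 -> Q1, 0 -> U. Per-
#' complex trajectories are monotone (a complex never rebinds).
#'
#' @param k_off_hr Unbinding rate constant, hr^-1.
#' @param n_complexes Number of complexes observed per window.
#' @param times_hr Observation window times, hours.
#' @param seed Optional RNG seed.
#' @return data.frame: `time_hr`, `N_Q2`, `N_Q1`, `N_U`.
#' @export
generate_unbinding_timeseries <- function(k_off_hr, n_complexes, times_hr,
                                          seed = NULL) {
    if (k_off_hr < 0) stop("k_off must be >= 0")
    with_seed(seed, {
        t1 <- if (k_off_hr > 0) rexp(n_complexes, k_off_hr) else rep(Inf, n_complexes)
        t2 <- if (k_off_hr > 0) rexp(n_complexes, k_off_hr) else rep(Inf, n_complexes)
        out <- lapply(times_hr, function(tt) {
            surv <- (t1 > tt) + (t2 > tt)
            data.frame(time_hr = tt,
                       N_Q2 = sum(surv == 2),
                       N_Q1 = sum(surv == 1),
                       N_U = sum(surv == 0))
        })
        do.call(rbind, out)
    })
}
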