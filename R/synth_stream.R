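#' Generate a synthetic photon stream for one photophysical state
#'
#' Emulates the two-polarization-channel photon record of a trapped particle:
#' photon arrivals are a homogeneous Poisson process at rate
#' `brightness x power + background`; each signal photon's TCSPC delay is an
#' exponential-mixture draw plus Gaussian IRF jitter (redrawn while negative,
#' preserving the mixture normalization), wrapped into the pulse window;
#' background photons carry uniform delays. Arrival times are quantized to
#' the 12.5 ns clock and delays to the 4 ps TCSPC grid. Channels are
#' assigned so the expected polarization matches the state's `fpol`.
#'
#' @param state A [pb_state()].
#' @param duration_s Stream duration, seconds.
#' @param power_uW Excitation power, uW.
#' @param background_cps Background count rate, cts s^-1 (default 25; kept
#'   low so the dimmest quenched state remains detectable).
#' @param irf_fwhm_ps Gaussian IRF FWHM, ps.
#' @param seed Optional RNG seed.
#' @param arrival_res_s Arrival-time quantization, s (12.5 ns).
#' @param delay_res_ns Delay quantization, ns (4 ps).
#' @param window_ns Pulse period / TCSPC window, ns.
#' @return data.frame of class `pb_photons`: `channel` ("parallel" /
#'   "perpendicular"), `arrival_s`, `delay_ns`, plus attribute `is_bg`.
#' @export
generate_photon_stream <- function(state, duration_s, power_uW,
                                   background_cps = 25, irf_fwhm_ps = 50,
                                   seed = NULL, arrival_res_s = 12.5e-9,
                                   delay_res_ns = 0.004, window_ns = 12.5) {
    if (duration_s <= 0 || power_uW <= 0) stop("duration and power must be > 0")
    if (background_cps < 0) stop("negative background rate")
    rate_sig <- state$brightness * power_uW
    rate_tot <- rate_sig + background_cps
    with_seed(seed, {
        n <- rpois(1, rate_tot * duration_s)
        t <- sort(runif(n, 0, duration_s))
        t <- round(t / arrival_res_s) * arrival_res_s
        is_bg <- runif(n) < background_cps / rate_tot
        delay <- numeric(n)
        ns <- sum(!is_bg)
        if (ns > 0)
            delay[!is_bg] <- sample_delays(ns, state$lifetime_components,
                                           irf_fwhm_ps, window_ns)
        nb <- sum(is_bg)
        if (nb > 0) delay[is_bg] <- runif(nb, 0, window_ns)
        # TCSPC convention: a delay is recorded as the 4 ps bin it falls in
        delay <- floor(delay / delay_res_ns) * delay_res_ns
        delay[delay >= window_ns] <- window_ns - delay_res_ns
        channel <- ifelse(runif(n) < (1 + state$fpol) / 2,
                          "parallel", "perpendicular")
        out <- data.frame(channel = channel, arrival_s = t, delay_ns = delay,
                          stringsAsFactors = FALSE)
        attr(out, "is_bg") <- is_bg
        class(out) <- c("pb_photons", "data.frame")
        out
    })
}

# Exponential-mixture delays with Gaussian IRF jitter; negative values are
# redrawn (whole draw), then wrapped into the pulse window.
sample_delays <- function(n, components, irf_fwhm_ps, window_ns) {
    sigma <- irf_fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
    draw <- function(m) {
        comp <- sample.int(nrow(components), m, replace = TRUE,
                           prob = components$amplitude)
        d <- rexp(m, rate = 1 / components$tau_ns[comp])
        if (sigma > 0) d <- d + rnorm(m, 0, sigma)
        d
    }
    d <- draw(n)
    for (it in 1:100) {
        neg <- d < 0
        if (!any(neg)) break
        d[neg] <- draw(sum(neg))
    }
    d[d < 0] <- 0
    d %% window_ns
}

#' Generate synthetic spectral camera frames
#'
#' Emulates the 50 Hz spectral channel: the stream is divided into 20 ms
#' frames; each photon deposits one count into a wavelength bin drawn from
#' its source spectrum (the state's Gaussian band mixture for signal photons,
#' flat for background photons).
#'
#' @param records A `pb_photons` stream.
#' @param state The [pb_state()] the stream was generated from, or a list of
#'   per-photon states (for multi-segment traces use [generate_trace()]).
#' @param seed Optional RNG seed.
#' @param frame_hz Camera frame rate (50 Hz).
#' @param lambda_grid Wavelength bin centers, nm.
#' @return Object of class `pb_frames`: list with `counts`
#'   (frames x bins integer matrix), `lambda_nm`, `frame_hz`.
#' @export
generate_spectral_frames <- function(records, state, seed = NULL,
                                     frame_hz = 50,
                                     lambda_grid = seq(600.25, 749.75, by = 0.5)) {
    with_seed(seed, {
        n <- nrow(records)
        is_bg <- attr(records, "is_bg") %||% rep(FALSE, n)
        w <- spectrum_weights(state$spectrum, lambda_grid)
        nf <- max(1, ceiling(max(records$arrival_s, 0) * frame_hz + 1e-9))
        counts <- matrix(0L, nrow = nf, ncol = length(lambda_grid))
        if (n > 0) {
            bin <- integer(n)
            if (any(!is_bg))
                bin[!is_bg] <- sample.int(length(lambda_grid), sum(!is_bg),
                                          replace = TRUE, prob = w)
            if (any(is_bg))
                bin[is_bg] <- sample.int(length(lambda_grid), sum(is_bg),
                                         replace = TRUE)
            fr <- pmin(floor(records$arrival_s * frame_hz) + 1L, nf)
            for (i in seq_len(n)) counts[fr[i], bin[i]] <- counts[fr[i], bin[i]] + 1L
        }
        structure(list(counts = counts, lambda_nm = lambda_grid,
                       frame_hz = frame_hz),
                  class = "pb_frames")
    })
}

spectrum_weights <- function(spectrum, lambda_grid) {
    w <- numeric(length(lambda_grid))
    for (i in seq_len(nrow(spectrum))) {
        sig <- spectrum$fwhm_nm[i] / (2 * sqrt(2 * log(2)))
        if (sig <= 0) {
            j <- which.min(abs(lambda_grid - spectrum$peak_nm[i]))
            w[j] <- w[j] + spectrum$weight[i]
        } else {
            d <- dnorm(lambda_grid, spectrum$peak_nm[i], sig)
            w <- w + spectrum$weight[i] * d / sum(d)
        }
    }
    w
}

#' Generate a multi-state trapping trace with ground truth
#'
#' Concatenates per-segment photon streams according to a truth table of
#' trapping events (state label, start, end); the gaps between segments
#' carry background-only photons, emulating the empty trap between captures.
#' Spectral frames are generated per photon from the active segment's
#' spectrum.
#'
#' @param truth data.frame with columns `state`, `start_s`, `end_s`
#'   (non-overlapping, ordered).
#' @param state_table Named list of [pb_state()] objects resolving the truth
#'   labels (e.g. `cbpb_reference_states()$states`).
#' @param power_uW Excitation power, uW.
#' @param background_cps Background rate, cts s^-1.
#' @param irf_fwhm_ps IRF FWHM, ps.
#' @param seed Optional RNG seed.
#' @param frame_hz,lambda_grid Spectral camera parameters.
#' @return List: `photons` (`pb_photons`), `frames` (`pb_frames`),
#'   `truth` (the input truth table).
#' @export
generate_trace <- function(truth, state_table, power_uW = 0.5,
                           background_cps = 25, irf_fwhm_ps = 50, seed = NULL,
                           frame_hz = 50,
                           lambda_grid = seq(600.25, 749.75, by = 0.5)) {
    if (nrow(truth) == 0) {
        empty <- data.frame(channel = character(), arrival_s = numeric(),
                            delay_ns = numeric(), stringsAsFactors = FALSE)
        class(empty) <- c("pb_photons", "data.frame")
        return(list(photons = empty,
                    frames = structure(list(counts = matrix(0L, 0, length(lambda_grid)),
                                            lambda_nm = lambda_grid,
                                            frame_hz = frame_hz),
                                       class = "pb_frames"),
                    truth = truth))
    }
    o <- order(truth$start_s)
    truth <- truth[o, , drop = FALSE]
    if (any(truth$end_s <= truth$start_s)) stop("segment end before start")
    if (nrow(truth) > 1 &&
        any(truth$start_s[-1] < truth$end_s[-nrow(truth)] - 1e-12))
        stop("overlapping segments in truth table")
    bad <- setdiff(truth$state, names(state_table))
    if (length(bad)) stop("unresolvable state label(s): ", paste(bad, collapse = ", "))
    bg_state <- pb_state("background", brightness = 0,
                         lifetime_components = data.frame(tau_ns = 1, amplitude = 1),
                         fpol = 0,
                         spectrum = data.frame(peak_nm = 675, fwhm_nm = 1e4, weight = 1))
    with_seed(seed, {
        pieces <- list()
        seg_of <- list()
        add_piece <- function(st, t0, t1, seg) {
            if (t1 <= t0) return()
            dur <- t1 - t0
            if (st$brightness * power_uW + background_cps <= 0) return()
            p <- generate_photon_stream(st, dur, power_uW, background_cps,
                                        irf_fwhm_ps, seed = NULL)
            if (nrow(p) == 0) return()
            bgflag <- attr(p, "is_bg")
            p$arrival_s <- p$arrival_s + t0
            pieces[[length(pieces) + 1]] <<- p
            seg_of[[length(seg_of) + 1]] <<-
                data.frame(seg = seg, is_bg = bgflag)
        }
        t_cursor <- 0
        for (i in seq_len(nrow(truth))) {
            if (truth$start_s[i] > t_cursor && background_cps > 0)
                add_piece(bg_state, t_cursor, truth$start_s[i], 0L)
            add_piece(state_table[[truth$state[i]]],
                      truth$start_s[i], truth$end_s[i], i)
            t_cursor <- truth$end_s[i]
        }
        photons <- do.call(rbind, pieces)
        segs <- do.call(rbind, seg_of)
        o2 <- order(photons$arrival_s)
        photons <- photons[o2, , drop = FALSE]
        segs <- segs[o2, , drop = FALSE]
        rownames(photons) <- NULL
        attr(photons, "is_bg") <- segs$is_bg
        attr(photons, "segment") <- segs$seg
        class(photons) <- c("pb_photons", "data.frame")
        # per-photon spectra: draw wavelength bins segment by segment
        n <- nrow(photons)
        nf <- max(1, ceiling(max(photons$arrival_s) * frame_hz + 1e-9))
        counts <- matrix(0L, nrow = nf, ncol = length(lambda_grid))
        bin <- integer(n)
        for (i in seq_len(nrow(truth))) {
            sel <- segs$seg == i & !segs$is_bg
            if (any(sel)) {
                w <- spectrum_weights(state_table[[truth$state[i]]]$spectrum,
                                      lambda_grid)
                bin[sel] <- sample.int(length(lambda_grid), sum(sel),
                                       replace = TRUE, prob = w)
            }
        }
        flat <- bin == 0L
        if (any(flat))
            bin[flat] <- sample.int(length(lambda_grid), sum(flat), replace = TRUE)
        fr <- pmin(floor(photons$arrival_s * frame_hz) + 1L, nf)
        for (i in seq_len(n)) counts[fr[i], bin[i]] <- counts[fr[i], bin[i]] + 1L
        frames <- structure(list(counts = counts, lambda_nm = lambda_grid,
                                 frame_hz = frame_hz),
                            class = "pb_frames")
        list(photons = photons, frames = frames, truth = truth)
    })
}
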