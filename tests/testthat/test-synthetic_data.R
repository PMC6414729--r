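test_that("photon streams respect quantization grids and rate fidelity", {
    st <- test_state(tau = 1.66, br = 10420)
    rec <- generate_photon_stream(st, duration_s = 1, power_uW = 0.16,
                                  background_cps = 0, irf_fwhm_ps = 50,
                                  seed = 101)
    # arrival clock 12.5 ns, delay grid 4 ps, arrivals non-decreasing
    expect_true(all(abs(rec$arrival_s / 12.5e-9 -
                            round(rec$arrival_s / 12.5e-9)) < 1e-6))
    expect_true(all(abs(rec$delay_ns / 0.004 -
                            round(rec$delay_ns / 0.004)) < 1e-9))
    expect_false(is.unsorted(rec$arrival_s))
    expect_true(all(rec$delay_ns >= 0 & rec$delay_ns < 12.5))
    # expected count 10420 * 0.16 = 1667 cts
    mu <- 10420 * 0.16
    expect_lt(abs(nrow(rec) - mu), 3 * sqrt(mu))
    expect_error(generate_photon_stream(st, 0, 0.16), "must be > 0")
})

test_that("channel split matches fpol and delays follow the lifetime mixture", {
    # fpol = 0: binomial channel split
    rec <- generate_photon_stream(test_state(br = 5000), 1, 1, 0, 50, seed = 102)
    npar <- sum(rec$channel == "parallel")
    expect_lt(abs(npar - nrow(rec) / 2), 3 * sqrt(nrow(rec) / 4))
    # fpol = 0.5 shifts the split to 75/25
    rec2 <- generate_photon_stream(test_state(br = 5000, fpol = 0.5), 1, 1, 0,
                                   50, seed = 103)
    expect_lt(abs(mean(rec2$channel == "parallel") - 0.75), 0.02)
    # zero-IRF delays are exponential: sample mean near tau (4 ps floor bias)
    rec3 <- generate_photon_stream(test_state(tau = 0.8, br = 20000), 1, 1, 0,
                                   irf_fwhm_ps = 0, seed = 104)
    expect_lt(abs(mean(rec3$delay_ns) + 0.002 - 0.8),
              3 * 0.8 / sqrt(nrow(rec3)) + 0.01)
})

test_that("spectral frames reproduce the state spectrum", {
    st <- test_state(br = 20000, lcm = 669)
    rec <- generate_photon_stream(st, 2, 0.5, 0, 50, seed = 105)
    fr <- generate_spectral_frames(rec, st, seed = 106)
    expect_s3_class(fr, "pb_frames")
    expect_equal(sum(fr$counts), nrow(rec))   # every photon lands in one bin
    expect_equal(fr$frame_hz, 50)
    # frame-summed center of mass near the analytic center
    tot <- colSums(fr$counts)
    sd_spec <- sqrt(sum(tot / sum(tot) * (fr$lambda_nm - 669)^2))
    expect_lt(abs(lambda_cm(tot, fr$lambda_nm) - 669),
              3 * sd_spec / sqrt(sum(tot)))
    # delta-function spectrum puts every count in one bin
    dst <- pb_state("d", 5000, data.frame(tau_ns = 1, amplitude = 1), 0,
                    data.frame(peak_nm = 660.25, fwhm_nm = 0, weight = 1))
    drec <- generate_photon_stream(dst, 0.5, 0.5, 0, 0, seed = 107)
    dfr <- generate_spectral_frames(drec, dst, seed = 108)
    expect_equal(sum(colSums(dfr$counts) > 0), 1)
    # a frame with no photons is all zeros
    empty_frames <- which(rowSums(dfr$counts) == 0)
    if (length(empty_frames))
        expect_true(all(dfr$counts[empty_frames[1], ] == 0))
})

test_that("generate_trace concatenates segments with background-only gaps", {
    states <- cbpb_reference_states()$states
    truth <- data.frame(state = c("Q2", "Q1", "Q2"),
                        start_s = c(0.5, 3, 5.5), end_s = c(2.5, 5, 7.5))
    tr <- generate_trace(truth, states, power_uW = 0.5, background_cps = 50,
                         seed = 109)
    expect_false(is.unsorted(tr$photons$arrival_s))
    seg <- attr(tr$photons, "segment")
    # photons in gaps are background (segment 0)
    gap <- tr$photons$arrival_s > 2.6 & tr$photons$arrival_s < 2.9
    expect_true(all(seg[gap] == 0))
    # segment photon rates reflect state brightness
    n_q2 <- sum(seg == 1)
    expect_lt(abs(n_q2 - 2 * (600 * 0.5 + 50)), 3 * sqrt(2 * 650) + 1)
    # overlap and unknown labels rejected
    expect_error(generate_trace(data.frame(state = c("Q1", "Q2"),
                                           start_s = c(0, 1), end_s = c(2, 3)),
                                states), "overlap")
    expect_error(generate_trace(data.frame(state = "XX", start_s = 0, end_s = 1),
                                states), "unresolvable")
    # empty truth gives empty outputs
    e <- generate_trace(truth[0, ], states)
    expect_equal(nrow(e$photons), 0)
})

test_that("bulk decay generation and fitting close the loop", {
    # single component, delta IRF: histogram is exponential
    h <- generate_bulk_decay(data.frame(tau_ns = 1.5, amplitude = 1),
                             2e5, irf_fwhm_ps = 0, seed = 110)
    m <- sum(h$mids_ns * h$counts) / sum(h$counts)
    # window-truncated exponential mean
    mt <- 1.5 - 12.5 * exp(-12.5 / 1.5) / (1 - exp(-12.5 / 1.5))
    expect_lt(abs(m - mt), 3 * 1.5 / sqrt(2e5) + 0.005)
    expect_error(generate_bulk_decay(data.frame(tau_ns = 1, amplitude = 0.5),
                                     10), "sum to 1")
    # Fisher errors blow up at tiny n
    comp <- data.frame(tau_ns = c(1.5, 0.1), amplitude = c(0.3, 0.7))
    big <- fit_lifetime_mle(generate_bulk_decay(comp, 1e5, 50, seed = 111),
                            irf_gaussian(50), 2)
    tiny <- fit_lifetime_mle(generate_bulk_decay(comp, 10, 50, seed = 112),
                             irf_gaussian(50), 2)
    expect_true(any(!is.finite(tiny$errors)) ||
                    length(tiny$flags) > 0 ||
                    all(tiny$errors >= 10 * big$errors))
})

test_that("rod brightness mixture and unbinding time series follow closed forms", {
    # single-species mixture is one Gaussian
    b1 <- generate_rod_brightness_sample(1500, 400, c(1, 0, 0), 2000, seed = 113)
    expect_lt(abs(mean(b1) - 1500), 3 * 400 / sqrt(2000))
    expect_lt(abs(sd(b1) - 400), 3 * 400 / sqrt(2 * 2000))
    expect_error(generate_rod_brightness_sample(1500, 400, c(1, 1, 1), 10),
                 "sum to 1")
    # unbinding: binomial(2, p) closed form at each time
    n <- 1e4
    ts <- generate_unbinding_timeseries(0.5, n, c(0, 1, 3), seed = 114)
    expect_equal(ts$N_Q2[1], n)    # t = 0: all doubly bound
    for (i in 2:3) {
        p <- exp(-0.5 * ts$time_hr[i])
        for (col in c("N_Q2", "N_Q1", "N_U")) {
            pe <- switch(col, N_Q2 = p^2, N_Q1 = 2 * p * (1 - p),
                         N_U = (1 - p)^2)
            expect_lt(abs(ts[[col]][i] - n * pe), 3 * sqrt(n * pe * (1 - pe)))
        }
    }
    # k_off t -> infinity: everything unbound
    far <- generate_unbinding_timeseries(5, 1000, 1000, seed = 115)
    expect_equal(far$N_U, 1000)
})
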