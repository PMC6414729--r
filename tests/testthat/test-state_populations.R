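ref_model <- cbpb_reference_states()$model

test_that("classification follows the ellipse, threshold and nearest-state rules", {
    params <- data.frame(Br = c(1160, 6000, 3000, 600, 10420),
                         tau_ns = c(0.21, 0.10, 5, 0.09, 1.66))
    lab <- classify_groups(params, ref_model)
    expect_equal(lab[1], "Q1")      # at the Q1 means
    expect_equal(lab[2], "U")       # bright groups are U regardless of tau
    expect_true(is.na(lab[3]))      # far from every state, below the U rule
    expect_equal(lab[4], "Q2")
    expect_equal(lab[5], "U")
    # ambiguous points resolve to the smallest Mahalanobis distance
    mid <- data.frame(Br = 900, tau_ns = 0.15)
    d2q1 <- br_tau_d2(900, 0.15, ref_model, "Q1")
    d2q2 <- br_tau_d2(900, 0.15, ref_model, "Q2")
    expect_equal(classify_groups(mid, ref_model),
                 if (d2q1 < d2q2) "Q1" else "Q2")
})

test_that("ellipse coverage is ~95% for draws from the state's own Gaussian", {
    set.seed(301)
    n <- 4000
    r <- ref_model[ref_model$state == "Q1", ]
    br <- rnorm(n, r$Br, r$Br_sd)
    tau <- rnorm(n, r$tau, r$tau_sd)
    inside <- br_tau_d2(br, tau, ref_model, "Q1") <= qchisq(0.95, 2)
    expect_lt(abs(mean(inside) - 0.95), 3 * sqrt(0.95 * 0.05 / n))
    e <- confidence_ellipse(ref_model, "Q1")
    expect_equal(e$center, c(r$Br, r$tau))
    expect_equal(e$radii, sqrt(qchisq(0.95, 2)) * c(r$Br_sd, r$tau_sd))
    expect_error(confidence_ellipse(ref_model, "Q1", coverage = 1.2), "coverage")
})

test_that("fit_state_gaussians recovers well-separated synthetic states", {
    set.seed(302)
    mk <- function(st, n) {
        r <- ref_model[ref_model$state == st, ]
        data.frame(Br = rnorm(n, r$Br, r$Br_sd),
                   tau_ns = rnorm(n, r$tau, r$tau_sd),
                   lambda_cm_nm = rnorm(n, r$lcm, r$lcm_sd),
                   FPol = rnorm(n, r$fpol, r$fpol_sd))
    }
    params <- rbind(mk("U", 300), mk("Q2", 300))
    labels <- rep(c("U", "Q2"), each = 300)
    fit <- fit_state_gaussians(params, labels)
    for (st in c("U", "Q2")) {
        r <- ref_model[ref_model$state == st, ]
        f <- fit[fit$state == st, ]
        expect_false(f$flagged)
        expect_lt(abs(f$Br - r$Br), 2 * r$Br_sd / sqrt(300) * 3)
        expect_lt(abs(f$tau - r$tau), 2 * r$tau_sd / sqrt(300) * 3)
        expect_lt(abs(f$Br_sd - r$Br_sd) / r$Br_sd, 0.3)
    }
    # one group only -> error; sparse state -> flagged
    expect_error(fit_state_gaussians(params[1, , drop = FALSE], "U"), "at least 2")
    sparse <- fit_state_gaussians(params[1:40, ], rep(c("U", "Q2"), each = 20))
    expect_true(all(sparse$flagged))
})

test_that("segment_levels forms maximal runs broken by unassigned groups", {
    expect_equal(nrow(segment_levels(c("Q2", "Q2", "Q2"))), 1)
    lev <- segment_levels(c("Q2", "Q2", "Q1", "Q1"))
    expect_equal(lev$state, c("Q2", "Q1"))
    expect_equal(lev$n_groups, c(2, 2))
    # unassigned groups break runs
    lev2 <- segment_levels(c("Q1", NA, "Q1"))
    expect_equal(nrow(lev2), 2)
    # level concatenation property when boundary labels differ
    a <- c("Q2", "Q2", "Q1")
    b <- c("U", "U")
    expect_equal(segment_levels(c(a, b))$state,
                 c(segment_levels(a)$state, segment_levels(b)$state))
    # censoring drops contiguous multi-state traces
    cens <- segment_levels(c("Q2", "Q2", "Q1", NA, "U"),
                           censor_transitions = TRUE)
    expect_equal(cens$state, "U")
    expect_equal(nrow(segment_levels(character())), 0)
})

test_that("population fractions carry binomial errors", {
    lev <- data.frame(state = c(rep("Q2", 10), rep("Q1", 0), "U"),
                      start_s = seq(0, 100, length.out = 11))
    f <- population_fractions(lev, window_s = 300)
    expect_equal(f$f_Q2, 1)
    expect_equal(f$f_U, 1 / 11)
    lev2 <- data.frame(state = c("Q1", "Q2", "Q1", "Q2"), start_s = 1:4)
    f2 <- population_fractions(lev2, window_s = 300)
    expect_equal(f2$f_Q2, 0.5)
    expect_equal(f2$f_Q2_err, sqrt(0.25 / 4))
    expect_error(population_fractions(lev2[0, ]), "no levels")
})

test_that("level segmentation recovers known segment counts from a trace", {
    states <- cbpb_reference_states()$states
    truth <- data.frame(state = c("Q2", "Q1", "Q2", "Q1"),
                        start_s = c(0, 6, 12, 18), end_s = c(5, 11, 17, 23))
    tr <- generate_trace(truth, states, power_uW = 0.5, background_cps = 10,
                         seed = 303)
    out <- analyze_photons(tr$photons, M = 200, power_uW = 0.5,
                           frames = NULL, fit_background = TRUE)
    lab <- classify_groups(out, ref_model)
    lev <- segment_levels(lab, out$t_mean_s)
    lev <- lev[lev$n_groups >= 2, ]   # singleton misassignments excluded
    expect_equal(nrow(lev), 4)
    expect_equal(lev$state, truth$state)
})

test_that("scatter_density matches a direct per-point count", {
    expect_equal(scatter_density(0, 0, 1, 1), 1)
    # far-apart points all have density 1 (only themselves)
    x <- seq(0, 90, by = 10)
    expect_true(all(scatter_density(x, x, 1, 1) == 1))
    set.seed(304)
    n <- 400
    x <- rnorm(n); y <- rnorm(n, sd = 2)
    dx <- 0.5 * sd(x); dy <- 0.5 * sd(y)
    d <- scatter_density(x, y, dx, dy)
    # independent double-loop oracle
    cnt <- integer(n)
    for (i in seq_len(n))
        cnt[i] <- sum(abs(x - x[i]) <= dx & abs(y - y[i]) <= dy)
    expect_equal(d, cnt / max(cnt))
    expect_equal(max(d), 1)
    # densest point sits near the center of the Gaussian cloud
    peak <- which.max(d)
    expect_lt(abs(x[peak] - mean(x)), 0.75 * sd(x))
    expect_lt(abs(y[peak] - mean(y)), 0.75 * sd(y))
})

test_that("constrained hexamer fit matches the profile-likelihood grid", {
    set.seed(305)
    br <- generate_rod_brightness_sample(1500, 400, rep(1, 3) / 3, 2500,
                                         seed = 306)
    fit <- fit_hexamer_mixture(br)
    expect_lt(abs(fit$br_1hex - 1500), 3 * max(fit$br_1hex_err, 20))
    # brute-force profile grid around the optimum agrees
    grid <- seq(1300, 1700, by = 10)
    prof <- hexamer_profile_loglik(br, grid)
    expect_lt(abs(prof$br_1hex[which.max(prof$loglik)] - fit$br_1hex), 15)
    # single-species data collapse onto one component
    b1 <- rnorm(500, 2000, 150)
    f1 <- fit_hexamer_mixture(b1)
    k <- which.max(f1$weights)
    expect_gt(f1$weights[k], 0.95)
    expect_lt(abs(k * f1$br_1hex - 2000), 50)
    expect_error(fit_hexamer_mixture(rnorm(20, 1000, 10)), "at least 100")
})
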