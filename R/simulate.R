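#' Sample initial absorption compartments
#'
#' Draws compartments from the network's absorption distribution (extinction
#' at the excitation wavelength normalized by the total complex extinction).
#'
#' @param net A `pb_network`.
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return Character vector of compartment ids.
#' @export
sample_absorption <- function(net, n, seed = NULL) {
    comp <- net$compartments
    with_seed(seed, {
        idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$absorption)
        comp$id[idx]
    })
}

sim_result <- function(net, absorbed_idx, terminal_idx, outcome, delay_ns,
                       sampler, dt_ns = NA_real_, seed = NA_integer_) {
    ids <- net$compartments$id
    events <- data.frame(
        absorbed = ids[absorbed_idx],
        terminal = ids[terminal_idx],
        outcome = c("radiative", "nonradiative", "quenched")[outcome],
        delay_ns = delay_ns,
        stringsAsFactors = FALSE)
    structure(list(events = events, n_events = nrow(events), seed = seed,
                   sampler = sampler, dt_ns = dt_ns, network = net),
              class = "pb_sim")
}

#' @export
print.pb_sim <- function(x, ...) {
    cat(sprintf("pb_sim: %d events (%s sampler)\n", x$n_events, x$sampler))
    print(table(x$events$outcome))
    invisible(x)
}

sim_inputs <- function(net) {
    comp <- net$compartments
    list(K = net$K,
         sink = comp$is_sink,
         g_rad = comp$decay_ns1 * comp$radiative_fraction,
         g_nr = comp$decay_ns1 * (1 - comp$radiative_fraction))
}

#' Fixed-step photon-by-photon exciton simulation
#'
#' Simulates each absorbed excitation as a discrete random walk with fixed
#' time steps `dt_ns`: in one step the excitation transfers i -> j with
#' probability `k[i,j] * dt`, decays radiatively with probability
#' `gamma_i * phi_i * dt`, nonradiatively with `gamma_i * (1 - phi_i) * dt`,
#' and otherwise stays. Decay and transfer compete within a single
#' categorical draw per step. The recorded delay is the number of elapsed
#' steps times `dt` (delays lie on the step grid). Entering an OCP sink
#' terminates the walk as "quenched".
#'
#' @param net A `pb_network`.
#' @param n_events Number of absorption events (the study's operating point
#'   is 1e5 per condition).
#' @param dt_ns Step size in ns; default 1e-4 (100 fs). Must satisfy
#'   `dt * max(total exit rate) <= 1`.
#' @param seed RNG seed for reproducibility.
#' @return A `pb_sim` result with one `EmissionEvent` row per excitation.
#' @export
simulate_fixed_step <- function(net, n_events, dt_ns = 1e-4, seed = NULL) {
    si <- sim_inputs(net)
    exit <- rowSums(si$K) + si$g_rad + si$g_nr
    if (dt_ns * max(exit) > 1)
        stop(sprintf("dt too large: max admissible dt = %.3g ns", 1 / max(exit)))
    if (n_events == 0)
        return(sim_result(net, integer(), integer(), integer(), numeric(),
                          "fixed_step", dt_ns))
    with_seed(seed, {
        start <- sample.int(nrow(net$compartments), n_events, replace = TRUE,
                            prob = net$compartments$absorption)
        w <- walk_fixed_step_cpp(si$K, si$sink, si$g_rad, si$g_nr,
                                 start - 1L, dt_ns)
        sim_result(net, start, w$terminal, w$outcome, w$steps * dt_ns,
                   "fixed_step", dt_ns, seed %||% NA_integer_)
    })
}

#' Exact continuous-time exciton simulation
#'
#' Statistically exact sampler for the same continuous-time chain solved by
#' [analytic_observables()]: exponential waiting times in each compartment
#' (rate = total exit rate) and categorical jumps. The recorded delay is the
#' exact sum of waiting times, free of discretization bias; used to bound the
#' O(dt) bias of the fixed-step sampler.
#'
#' @inheritParams simulate_fixed_step
#' @return A `pb_sim` result.
#' @export
simulate_exact <- function(net, n_events, seed = NULL) {
    si <- sim_inputs(net)
    tr <- !si$sink
    exit <- rowSums(si$K) + si$g_rad + si$g_nr
    if (any(exit[tr] <= 0))
        stop("non-absorbing chain: zero exit rate in ",
             paste(net$compartments$id[tr][exit[tr] <= 0], collapse = ", "))
    if (n_events == 0)
        return(sim_result(net, integer(), integer(), integer(), numeric(),
                          "exact"))
    with_seed(seed, {
        start <- sample.int(nrow(net$compartments), n_events, replace = TRUE,
                            prob = net$compartments$absorption)
        w <- walk_exact_cpp(si$K, si$sink, si$g_rad, si$g_nr, start - 1L)
        sim_result(net, start, w$terminal, w$outcome, w$delay, "exact",
                   seed = seed %||% NA_integer_)
    })
}

#' Empirical yields and standard errors from a simulation
#'
#' @param sim A `pb_sim` result.
#' @return data.frame with outcome, estimated probability, and binomial
#'   standard error.
#' @export
sim_yields <- function(sim) {
    n <- sim$n_events
    out <- factor(sim$events$outcome,
                  levels = c("radiative", "nonradiative", "quenched"))
    p <- as.numeric(table(out)) / n
    data.frame(outcome = levels(out), p = p, se = sqrt(p * (1 - p) / n))
}

#' Derive photophysical observables from a simulation
#'
#' Runs simulated emission through the same quantities measured for a trapped
#' particle: absolute brightness (cts s^-1 uW^-1) via a calibrated scale,
#' a single-exponential maximum-likelihood lifetime fitted to the radiative
#' delays, the composite emission spectrum (emission-distribution-weighted
#' sum of per-class basis spectra), and its spectral center of mass.
#'
#' @param sim A `pb_sim` result.
#' @param brightness_scale cts s^-1 uW^-1 per unit (extinction x yield); see
#'   [calibrate_brightness_scale()].
#' @param lambda_grid Wavelength grid for the composite spectrum, nm.
#' @param irf Instrument response used in the lifetime fit; default is a
#'   delta IRF since simulated delays are unblurred.
#' @return List with `Br`, `tau_ns`, `tau_err`, `spectrum`, `lambda_cm_nm`,
#'   and the empirical `yields` table.
#' @export
derive_observables <- function(sim, brightness_scale,
                               lambda_grid = seq(600, 750, by = 0.5),
                               irf = irf_gaussian(0)) {
    ev <- sim$events
    rad <- ev[ev$outcome == "radiative", , drop = FALSE]
    if (!nrow(rad)) stop("no radiative events: observables undefined")
    net <- sim$network
    y_hat <- nrow(rad) / sim$n_events
    br <- brightness_scale * net$total_extinction * y_hat
    fit <- fit_lifetime_mle(rad$delay_ns, irf = irf, n_components = 1)
    # empirical emission distribution over pigment classes
    cls <- net$compartments$class[match(rad$terminal, net$compartments$id)]
    w <- table(cls) / nrow(rad)
    dens <- numeric(length(lambda_grid))
    for (cn in names(w)) {
        sp <- net$spectra[[cn]]
        if (is.null(sp)) stop("no basis spectrum for pigment class ", cn)
        sig <- sp$fwhm_nm / (2 * sqrt(2 * log(2)))
        d <- dnorm(lambda_grid, sp$peak_nm, sig)
        dens <- dens + as.numeric(w[[cn]]) * d / sum(d)
    }
    spec <- data.frame(lambda_nm = lambda_grid, intensity = dens / sum(dens))
    list(Br = br, tau_ns = fit$taus, tau_err = fit$errors,
         spectrum = spec, lambda_cm_nm = lambda_cm(spec$intensity, spec$lambda_nm),
         yields = sim_yields(sim))
}

#' Group simulated radiative photons and compute per-group (Br, tau)
#'
#' Emulates the M-photon grouping of trapped-particle analysis on simulated
#' emission: consecutive radiative events are grouped M at a time; since
#' absorption events arrive at a constant excitation rate, the number of
#' absorption events spanned by a group is the simulation's clock, so the
#' group brightness is `scale * extinction * M / n_absorptions`. The group
#' lifetime is a single-exponential MLE on the M delays.
#'
#' @param sim A `pb_sim` result.
#' @param M Photons per group (e.g. 200).
#' @param brightness_scale See [calibrate_brightness_scale()].
#' @return data.frame: group, Br, tau_ns.
#' @export
sim_photon_groups <- function(sim, M, brightness_scale) {
    ev <- sim$events
    rad_idx <- which(ev$outcome == "radiative")
    ng <- length(rad_idx) %/% M
    if (ng == 0) stop("fewer than M radiative events")
    out <- vector("list", ng)
    for (g in seq_len(ng)) {
        sel <- rad_idx[((g - 1) * M + 1):(g * M)]
        span <- sel[length(sel)] - sel[1] + 1   # absorption events spanned
        d <- ev$delay_ns[sel]
        fit <- fit_lifetime_mle(d, irf = irf_gaussian(0), n_components = 1)
        out[[g]] <- data.frame(group = g,
                               Br = brightness_scale * sim$network$total_extinction * M / span,
                               tau_ns = fit$taus)
    }
    do.call(rbind, out)
}

#' Sweep quencher strength over attachment site sets
#'
#' For each site set and each quenching rate, attaches OCP sinks and reports
#' the analytic relative brightness, absolute brightness under the supplied
#' scale, conditional mean radiative delay, and spectral center of mass.
#'
#' @param net Unquenched reference `pb_network`.
#' @param site_sets List of character vectors of sites, e.g.
#'   `list("a", c("a", "d"))`.
#' @param kq_grid Quenching rates, ns^-1.
#' @param br_reference Brightness assigned to the unquenched reference.
#' @return Tidy data.frame: site_set, k_q, rel_brightness, Br, tau_ns,
#'   lambda_cm_nm.
#' @export
quencher_sweep <- function(net, site_sets, kq_grid,
                           br_reference = 10420) {
    scale <- calibrate_brightness_scale(net, br_reference)
    rows <- list()
    for (ss in site_sets) {
        for (kq in kq_grid) {
            qnet <- attach_quenchers(net, data.frame(site = ss, k_q = kq))
            obs <- analytic_observables(qnet)
            spec <- network_emission_spectrum(qnet, obs = obs)
            rows[[length(rows) + 1]] <- data.frame(
                site_set = paste(ss, collapse = ""),
                k_q = kq,
                rel_brightness = relative_brightness(qnet, net),
                Br = scale * qnet$total_extinction * obs$yield_radiative,
                tau_ns = obs$mean_delay_ns,
                lambda_cm_nm = lambda_cm(spec$intensity, spec$lambda_nm))
        }
    }
    do.call(rbind, rows)
}
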