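# Hand-built toy networks and small fixtures shared across tests.

toy_single <- function(gamma = 1, phi = 0.5, ext = 1) {
    build_model(list(
        name = "single compartment",
        compartments = list(list(id = "x", class = "CPC650", extinction = ext,
                                 decay_ns1 = gamma, radiative_fraction = phi)),
        rates = list(),
        spectra = list(CPC650 = list(peak_nm = 650, fwhm_nm = 25))))
}

# linear 3-compartment chain r1 <-> c <- r2-ish with asymmetric rates
toy_chain3 <- function(gamma = c(0.8, 0.5, 1.2), phi = c(0.5, 0.4, 0.6)) {
    build_model(list(
        name = "chain3",
        compartments = list(
            list(id = "p", class = "CPC650", extinction = 0.5,
                 decay_ns1 = gamma[1], radiative_fraction = phi[1]),
            list(id = "q", class = "APC660", extinction = 0.3,
                 decay_ns1 = gamma[2], radiative_fraction = phi[2]),
            list(id = "r", class = "APC680", extinction = 0.2,
                 decay_ns1 = gamma[3], radiative_fraction = phi[3])),
        rates = list(list(from = "p", to = "q", k_ns1 = 3),
                     list(from = "q", to = "p", k_ns1 = 1),
                     list(from = "q", to = "r", k_ns1 = 5),
                     list(from = "r", to = "q", k_ns1 = 2)),
        spectra = list(CPC650 = list(peak_nm = 650, fwhm_nm = 25),
                       APC660 = list(peak_nm = 660, fwhm_nm = 28),
                       APC680 = list(peak_nm = 680, fwhm_nm = 26))))
}

# random small connected network for property-style loops
random_toy_network <- function(n = 4) {
    ids <- letters[seq_len(n)]
    comps <- lapply(seq_len(n), function(i)
        list(id = ids[i], class = "APC660", extinction = runif(1, 0.1, 1),
             decay_ns1 = runif(1, 0.2, 2), radiative_fraction = runif(1)))
    rates <- list()
    for (i in seq_len(n - 1)) {   # chain backbone keeps it connected
        rates[[length(rates) + 1]] <- list(from = ids[i], to = ids[i + 1],
                                           k_ns1 = runif(1, 0.5, 20))
        rates[[length(rates) + 1]] <- list(from = ids[i + 1], to = ids[i],
                                           k_ns1 = runif(1, 0.5, 20))
    }
    build_model(list(name = "random toy", compartments = comps, rates = rates,
                     quench_sites = as.list(ids),
                     spectra = list(APC660 = list(peak_nm = 660, fwhm_nm = 28))))
}

# state used for quick synthetic streams
test_state <- function(tau = 1.66, br = 10420, fpol = 0, lcm = 669) {
    pb_state("T", br, data.frame(tau_ns = tau, amplitude = 1), fpol,
             spectrum = data.frame(peak_nm = c(650, 680), fwhm_nm = c(25, 22),
                                   weight = c((680 - lcm) / 30,
                                              1 - (680 - lcm) / 30)))
}

q2_sites <- list(ad = c("a", "d"), apdp = c("a'", "d'"),
                 bc = c("b", "c"), ef = c("e", "f"))

# squared axis-aligned Mahalanobis radius in the Br-tau plane
br_tau_d2 <- function(br, tau, model, state) {
    r <- model[model$state == state, ]
    ((br - r$Br) / r$Br_sd)^2 + ((tau - r$tau) / r$tau_sd)^2
}
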