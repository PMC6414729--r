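test_that("build_model validates configurations", {
    net <- default_network()
    # the 8 labeled core quenching sites plus C-PC rod hexamers are present
    expect_setequal(net$quench_sites, c("a", "b", "c", "d", "e", "f", "a'", "d'"))
    expect_true(all(net$quench_sites %in% net$compartments$id))
    expect_true(any(grepl("^CPC-", net$compartments$id)))
    expect_equal(sum(net$compartments$absorption), 1, tolerance = 1e-12)

    one <- toy_single()
    expect_s3_class(one, "pb_network")
    expect_equal(nrow(one$compartments), 1)

    bad <- list(compartments = list(list(id = "x", class = "CPC650",
                                         extinction = 1, decay_ns1 = 1,
                                         radiative_fraction = 0.5)),
                rates = list(list(from = "x", to = "x", k_ns1 = -1)))
    expect_error(build_model(bad), "egative")
    bad$rates <- list(list(from = "x", to = "nope", k_ns1 = 1))
    expect_error(build_model(bad), "unknown compartment")
    bad$rates <- list()
    bad$compartments[[1]]$extinction <- 0
    expect_error(build_model(bad), "normalizable")
})

test_that("attach_quenchers adds isolated sinks and leaves the input unchanged", {
    net <- default_network()
    q <- attach_quenchers(net, data.frame(site = "a", k_q = 540))
    expect_equal(nrow(q$compartments), nrow(net$compartments) + 1)
    sink_row <- q$K["OCP:a", ]
    expect_true(all(sink_row == 0))           # no back transfer
    expect_equal(q$K["a", "OCP:a"], 540)
    expect_equal(sum(q$K[, "OCP:a"] > 0), 1)  # reachable only from its site
    expect_false("OCP:a" %in% net$compartments$id)  # original unmodified

    expect_error(attach_quenchers(net, data.frame(site = c("a", "a"),
                                                  k_q = c(1, 2))), "duplicate")
    expect_error(attach_quenchers(net, data.frame(site = "zz", k_q = 1)),
                 "unknown")

    # zero-rate attachment is inert
    q0 <- attach_quenchers(net, data.frame(site = "a", k_q = 0))
    o0 <- analytic_observables(q0)
    ou <- analytic_observables(net)
    expect_equal(o0$yield_radiative, ou$yield_radiative, tolerance = 1e-12)
    expect_equal(o0$mean_delay_ns, ou$mean_delay_ns, tolerance = 1e-12)
})

test_that("analytic_observables matches closed forms on toy networks", {
    # single compartment: simple branching and single-exponential delay
    o <- analytic_observables(toy_single(gamma = 1, phi = 0.5))
    expect_equal(o$yield_radiative, 0.5, tolerance = 1e-12)
    expect_equal(o$yield_nonradiative, 0.5, tolerance = 1e-12)
    expect_equal(o$yield_quenched, 0, tolerance = 1e-12)
    expect_equal(o$mean_delay_ns, 1, tolerance = 1e-12)

    # competing first-order rates with a sink
    oq <- analytic_observables(
        attach_quenchers(toy_single(gamma = 1, phi = 0.5),
                         data.frame(site = "x", k_q = 1)))
    expect_equal(oq$yield_radiative, 0.25, tolerance = 1e-12)
    expect_equal(oq$yield_quenched, 0.5, tolerance = 1e-12)
    expect_equal(oq$mean_delay_ns, 0.5, tolerance = 1e-12)

    # uniform-decay default: amplitude-weighted unquenched lifetime is 1.66 ns
    ou <- analytic_observables(default_network())
    expect_equal(ou$mean_delay_ns, 1.66, tolerance = 1e-9)
    expect_equal(sum(ou$emission_distribution), 1, tolerance = 1e-9)

    # trapped-forever detection
    cfg <- list(compartments = list(list(id = "x", class = "CPC650",
                                         extinction = 1, decay_ns1 = 0,
                                         radiative_fraction = 0.5)),
                rates = list())
    expect_error(analytic_observables(build_model(cfg)), "trapped forever")
})

test_that("yield conservation holds across random networks and attachments", {
    set.seed(402)
    for (i in 1:20) {
        net <- random_toy_network(n = sample(2:5, 1))
        if (i %% 2 == 0)
            net <- attach_quenchers(net, data.frame(
                site = sample(net$compartments$id[!net$compartments$is_sink], 1),
                k_q = runif(1, 0, 300)))
        o <- analytic_observables(net)
        expect_equal(o$yield_radiative + o$yield_nonradiative + o$yield_quenched,
                     1, tolerance = 1e-9)
        if (o$yield_radiative > 0) {
            expect_equal(sum(o$emission_distribution), 1, tolerance = 1e-9)
            expect_gt(o$mean_delay_ns, 0)
        }
    }
})

test_that("C2 symmetry: observables invariant under a<->d, b<->c, e<->f, a'<->d'", {
    net <- default_network()
    swap <- c(a = "d", d = "a", b = "c", c = "b", e = "f", f = "e",
              "a'" = "d'", "d'" = "a'")
    for (sites in list("a", c("a", "c"), c("a'", "e"), c("b", "d'"))) {
        k <- 540
        o1 <- analytic_observables(attach_quenchers(net, data.frame(site = sites, k_q = k)))
        o2 <- analytic_observables(attach_quenchers(net, data.frame(site = unname(swap[sites]), k_q = k)))
        expect_equal(o1$yield_radiative, o2$yield_radiative, tolerance = 1e-9)
        expect_equal(o1$yield_quenched, o2$yield_quenched, tolerance = 1e-9)
        expect_equal(o1$mean_delay_ns, o2$mean_delay_ns, tolerance = 1e-9)
    }
})

test_that("quenching dominance: pairs quench at least as hard as either single site", {
    net <- default_network()
    for (k in c(30, 540)) {
        for (pr in q2_sites) {
            yp <- analytic_observables(
                attach_quenchers(net, data.frame(site = pr, k_q = k)))$yield_radiative
            y1 <- analytic_observables(
                attach_quenchers(net, data.frame(site = pr[1], k_q = k)))$yield_radiative
            y2 <- analytic_observables(
                attach_quenchers(net, data.frame(site = pr[2], k_q = k)))$yield_radiative
            expect_lte(yp, min(y1, y2) + 1e-12)
        }
    }
})

test_that("relative_brightness handles identity, quenching limit, and sinks", {
    net <- default_network()
    expect_equal(relative_brightness(net, net), 1, tolerance = 1e-12)
    # perfect-sink limit: quench every pigment compartment very hard
    allq <- attach_quenchers(net, data.frame(
        site = net$compartments$id[!net$compartments$is_sink], k_q = 1e7))
    expect_lt(relative_brightness(allq, net), 1e-3)
    # zero-brightness reference errors
    dark <- toy_single(phi = 0)
    expect_error(relative_brightness(net, dark), "zero")
})

test_that("attach_core_quencher quenches all core compartments at once", {
    net <- default_network()
    g <- attach_core_quencher(net, 54)
    o <- analytic_observables(g)
    expect_gt(o$yield_quenched, 0.5)
    expect_lt(o$mean_delay_ns, analytic_observables(net)$mean_delay_ns)
})
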