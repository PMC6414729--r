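#' Build a compartmental exciton-transfer network
#'
#' Constructs a validated `pb_network` from a model-configuration document.
#' A configuration lists pigment compartments (id, pigment class, extinction
#' weight at the excitation wavelength, intrinsic decay rate in ns^-1,
#' radiative fraction), the directed inter-compartment transfer rates, the
#' set of admissible quencher attachment sites, and optionally per-class
#' Gaussian emission spectra.
#'
#' The default CB-PB configuration shipped with the package
#' (`default_network()`) represents the truncated single-hexamer-rod
#' phycobilisome: a core of three cylinders whose hexamers are labelled
#' `a`--`f` (with `a'`/`d'` the red-shifted terminal-emitter subunits of the
#' bottom-cylinder discs `a`/`d`), each core hexamer fed by one C-PC rod
#' hexamer. Extinction weights are normalized into absorption probabilities;
#' the raw total is retained so that brightness can be compared across
#' complexes of different size (e.g. a detached C-PC hexamer).
#'
#' @param config Path to a JSON configuration file, or an equivalent list.
#' @return An object of class `pb_network` with elements `compartments`
#'   (data.frame: id, class, extinction, absorption, decay_ns1,
#'   radiative_fraction, is_sink), `K` (directed rate matrix, ns^-1),
#'   `total_extinction`, `quench_sites`, and `spectra`.
#' @export
build_model <- function(config) {
    if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
    if (!is.list(config) || is.null(config$compartments))
        stop("configuration must list compartments")
    comp <- do.call(rbind, lapply(config$compartments, function(cc) {
        data.frame(id = as.character(cc$id),
                   class = as.character(cc$class %||% "pigment"),
                   extinction = as.numeric(cc$extinction %||% cc$absorption %||% 0),
                   decay_ns1 = as.numeric(cc$decay_ns1 %||% 0),
                   radiative_fraction = as.numeric(cc$radiative_fraction %||% 0),
                   stringsAsFactors = FALSE)
    }))
    comp$is_sink <- comp$class == "OCP-sink"
    if (anyDuplicated(comp$id)) stop("duplicate compartment ids in configuration")
    n <- nrow(comp)
    K <- matrix(0, n, n, dimnames = list(comp$id, comp$id))
    for (r in config$rates %||% list()) {
        fi <- match(as.character(r$from), comp$id)
        ti <- match(as.character(r$to), comp$id)
        if (is.na(fi) || is.na(ti))
            stop("unknown compartment reference in rates: ", r$from, " -> ", r$to)
        k <- as.numeric(r$k_ns1)
        if (is.na(k) || k < 0)
            stop("negative or missing rate for ", r$from, " -> ", r$to)
        K[fi, ti] <- k
    }
    spectra <- lapply(config$spectra %||% list(), function(s)
        list(peak_nm = as.numeric(s$peak_nm), fwhm_nm = as.numeric(s$fwhm_nm)))
    net <- structure(list(
        name = config$name %||% "unnamed",
        compartments = comp,
        K = K,
        total_extinction = sum(comp$extinction),
        quench_sites = as.character(unlist(config$quench_sites %||% character())),
        spectra = spectra
    ), class = "pb_network")
    validate_network(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pb_network
#'
#' Checks the structural invariants: nonnegative rates and decay rates,
#' radiative fractions in \[0, 1\], normalizable extinction weights,
#' zero absorption on OCP sinks, and no back transfer out of OCP sinks.
#'
#' @param net A `pb_network`.
#' @return The network, invisibly-validated, with `absorption` normalized.
#' @export
validate_network <- function(net) {
    comp <- net$compartments
    if (any(comp$decay_ns1 < 0)) stop("negative intrinsic decay rate")
    if (any(comp$radiative_fraction < 0 | comp$radiative_fraction > 1))
        stop("radiative_fraction outside [0, 1]")
    if (any(net$K < 0)) stop("negative transfer rate")
    if (any(comp$extinction < 0)) stop("negative extinction weight")
    if (any(comp$extinction[comp$is_sink] != 0))
        stop("OCP-sink compartments must have zero absorption")
    tot <- sum(comp$extinction)
    if (!(tot > 0)) stop("absorption weights not normalizable (total <= 0)")
    if (any(abs(net$K[comp$is_sink, , drop = FALSE]) > 0))
        stop("back transfer from an OCP sink is not permitted")
    net$compartments$absorption <- comp$extinction / tot
    stopifnot(abs(sum(net$compartments$absorption) - 1) < 1e-9)
    net
}

#' @export
print.pb_network <- function(x, ...) {
    cat("pb_network:", x$name, "\n")
    cat("  compartments:", nrow(x$compartments),
        sprintf("(%d OCP sinks)", sum(x$compartments$is_sink)), "\n")
    cat("  directed rates:", sum(x$K > 0), "\n")
    cat("  total extinction (relative):", format(x$total_extinction), "\n")
    invisible(x)
}

#' Attach OCP quenchers to a network
#'
#' Adds one non-emissive OCP sink per attachment. Each sink is reachable only
#' from its attachment site, at the forward quenching rate `k_q` (ns^-1);
#' no back transfer out of the sink is permitted, so an excitation entering
#' the sink terminates immediately as "quenched". The input network is not
#' modified.
#'
#' @param net A `pb_network`.
#' @param attachments A data.frame with columns `site` and `k_q`, or a list
#'   of `list(site =, k_q =)` entries.
#' @return A new `pb_network` with the sinks added.
#' @export
attach_quenchers <- function(net, attachments) {
    if (is.data.frame(attachments)) {
        att <- attachments
    } else {
        att <- do.call(rbind, lapply(attachments, function(a)
            data.frame(site = as.character(a$site), k_q = as.numeric(a$k_q),
                       stringsAsFactors = FALSE)))
    }
    if (is.null(att) || nrow(att) == 0) return(net)
    if (anyDuplicated(att$site)) stop("duplicate quencher attachment site")
    comp <- net$compartments
    bad <- setdiff(att$site, comp$id[!comp$is_sink])
    if (length(bad)) stop("unknown attachment site: ", paste(bad, collapse = ", "))
    if (any(att$k_q < 0)) stop("k_q must be >= 0")
    n0 <- nrow(comp)
    na <- nrow(att)
    sink_ids <- paste0("OCP:", att$site)
    comp2 <- rbind(comp, data.frame(
        id = sink_ids, class = "OCP-sink", extinction = 0, decay_ns1 = 0,
        radiative_fraction = 0, is_sink = TRUE, absorption = 0))
    K2 <- matrix(0, n0 + na, n0 + na, dimnames = list(comp2$id, comp2$id))
    K2[1:n0, 1:n0] <- net$K
    for (i in seq_len(na))
        K2[att$site[i], sink_ids[i]] <- att$k_q[i]
    net2 <- net
    net2$compartments <- comp2
    net2$K <- K2
    validate_network(net2)
}

#' Attach a single global core quencher
#'
#' Alternative quenching mode in which one OCP sink is reachable from every
#' core (APC-class) compartment simultaneously at rate `k_q`. Provided for
#' comparison with compartment-specific attachment; not used by the default
#' analyses.
#'
#' @param net A `pb_network`.
#' @param k_q Forward quenching rate, ns^-1, applied from every APC660/APC680
#'   compartment.
#' @return A new `pb_network`.
#' @export
attach_core_quencher <- function(net, k_q) {
    if (k_q < 0) stop("k_q must be >= 0")
    comp <- net$compartments
    core <- comp$id[comp$class %in% c("APC660", "APC680")]
    if (!length(core)) stop("network has no core (APC) compartments")
    n0 <- nrow(comp)
    comp2 <- rbind(comp, data.frame(
        id = "OCP:core", class = "OCP-sink", extinction = 0, decay_ns1 = 0,
        radiative_fraction = 0, is_sink = TRUE, absorption = 0))
    K2 <- matrix(0, n0 + 1, n0 + 1, dimnames = list(comp2$id, comp2$id))
    K2[1:n0, 1:n0] <- net$K
    K2[core, "OCP:core"] <- k_q
    net2 <- net
    net2$compartments <- comp2
    net2$K <- K2
    validate_network(net2)
}

#' Default CB-PB network
#'
#' Loads the synthetic default CB-PB model configuration shipped in
#' `inst/extdata/cbpb_synthetic_default.json`. See the configuration file
#' and the methods vignette for the assumed core adjacency and the one-time
#' rate calibration; the file is the single source of truth for all rate
#' values.
#'
#' @return A `pb_network`.
#' @export
default_network <- function() {
    build_model(system.file("extdata", "cbpb_synthetic_default.json",
                            package = "pbexciton", mustWork = TRUE))
}

#' Single detached C-PC hexamer network
#'
#' One-compartment network reusing the C-PC class parameters of a reference
#' configuration: the model for the "blue" detached-hexamer state B.
#'
#' @param net Reference `pb_network` supplying the C-PC parameters (default:
#'   `default_network()`).
#' @return A `pb_network` with a single CPC650 compartment.
#' @export
cpc_hexamer_network <- function(net = default_network()) {
    comp <- net$compartments
    cpc <- comp[comp$class == "CPC650", , drop = FALSE]
    if (!nrow(cpc)) stop("reference network has no CPC650 compartment")
    cfg <- list(
        name = "single C-PC hexamer",
        compartments = list(list(
            id = "CPC", class = "CPC650", extinction = cpc$extinction[1],
            decay_ns1 = cpc$decay_ns1[1],
            radiative_fraction = cpc$radiative_fraction[1])),
        rates = list(),
        spectra = net$spectra
    )
    build_model(cfg)
}
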