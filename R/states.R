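#' Fit per-state Gaussians to grouped parameters
#'
#' For each state and each of the four dimensions (Br, tau, lambda_CM, FPol),
#' forms a histogram of the per-group values and fits a Gaussian by weighted
#' least squares to determine the most probable value and standard
#' deviation, falling back to the sample mean/sd if the histogram fit is
#' degenerate.
#'
#' @param params Per-group parameter table ([analyze_photons()] output).
#' @param labels Character vector of state labels per group.
#' @param min_groups Minimum groups per state for a stable fit (default 30;
#'   states below it are flagged).
#' @return A `pb_state_model` data.frame: state, Br, Br_sd, tau, tau_sd,
#'   lcm, lcm_sd, fpol, fpol_sd, n, flagged.
#' @export
fit_state_gaussians <- function(params, labels, min_groups = 30) {
    if (nrow(params) < 2) stop("need at least 2 groups to fit state Gaussians")
    dims <- c(Br = "Br", tau = "tau_ns", lcm = "lambda_cm_nm", fpol = "FPol")
    sts <- sort(unique(labels[!is.na(labels)]))
    rows <- lapply(sts, function(s) {
        sel <- which(labels == s)
        row <- list(state = s, n = length(sel), flagged = length(sel) < min_groups)
        for (d in names(dims)) {
            x <- params[[dims[[d]]]][sel]
            x <- x[is.finite(x)]
            g <- if (length(x) >= 2) gaussian_hist_fit(x) else
                list(mean = if (length(x)) x else NA_real_, sd = NA_real_)
            row[[d]] <- g$mean
            row[[paste0(d, "_sd")]] <- g$sd
        }
        as.data.frame(row)
    })
    out <- do.call(rbind, rows)
    structure(out[, c("state", "Br", "Br_sd", "tau", "tau_sd", "lcm",
                      "lcm_sd", "fpol", "fpol_sd", "n", "flagged")],
              class = c("pb_state_model", "data.frame"))
}

# Histogram-based Gaussian fit of one dimension: least squares of
# A exp(-(x-mu)^2 / 2 sigma^2) against histogram counts.
gaussian_hist_fit <- function(x) {
    m0 <- mean(x); s0 <- sd(x)
    if (!is.finite(s0) || s0 <= 0)
        return(list(mean = m0, sd = max(s0, 0)))
    nb <- max(10, grDevices::nclass.FD(x))
    h <- graphics::hist(x, breaks = nb, plot = FALSE)
    mid <- h$mids; cnt <- h$counts
    obj <- function(th) {
        mu <- th[1]; lsig <- th[2]; lA <- th[3]
        pred <- exp(lA) * exp(-(mid - mu)^2 / (2 * exp(2 * lsig)))
        sum((pred - cnt)^2)
    }
    op <- tryCatch(optim(c(m0, log(s0), log(max(cnt))), obj,
                         control = list(maxit = 500)),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value))
        return(list(mean = m0, sd = s0))
    mu <- op$par[1]; sig <- exp(op$par[2])
    # reject degenerate fits that wandered off the data
    if (mu < min(x) || mu > max(x) || sig > 5 * s0 || sig < s0 / 20)
        return(list(mean = m0, sd = s0))
    list(mean = mu, sd = sig)
}

#' 95% confidence ellipse of a state in a 2-D projection
#'
#' Axis-aligned ellipse from the state's per-dimension Gaussians: squared
#' Mahalanobis radius `(x-mu_x)^2/sig_x^2 + (y-mu_y)^2/sig_y^2 <=
#' qchisq(coverage, 2)` (5.991 at 95%).
#'
#' @param model A `pb_state_model`.
#' @param state State label.
#' @param dims Two of `c("Br", "tau", "lcm", "fpol")`.
#' @param coverage Coverage level in (0, 1).
#' @return List: `center`, `radii` (semi-axes), `coverage`.
#' @export
confidence_ellipse <- function(model, state, dims = c("Br", "tau"),
                               coverage = 0.95) {
    if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0,1)")
    r <- model[model$state == state, , drop = FALSE]
    if (!nrow(r)) stop("unknown state ", state)
    mu <- c(r[[dims[1]]], r[[dims[2]]])
    sig <- c(r[[paste0(dims[1], "_sd")]], r[[paste0(dims[2], "_sd")]])
    if (any(sig <= 0)) stop("nonpositive sigma in state model")
    k <- sqrt(qchisq(coverage, df = 2))
    list(center = mu, radii = k * sig, coverage = coverage)
}

#' Classify photon groups into photophysical states
#'
#' Membership is tested in the Br-tau plane against each state's 95%
#' confidence ellipse (axis-aligned, chi-square with 2 d.o.f.); a group
#' inside several ellipses takes the smallest Mahalanobis distance; a group
#' with brightness above `br_u_threshold` (5000 cts s^-1 uW^-1) is assigned
#' U regardless; a group inside no ellipse is unassigned (NA).
#'
#' @param params Per-group parameter table with `Br` and `tau_ns`.
#' @param model A `pb_state_model`.
#' @param coverage Ellipse coverage (default 0.95).
#' @param br_u_threshold Brightness above which a group is forced to U.
#' @return Character vector of state labels (NA = unassigned).
#' @export
classify_groups <- function(params, model, coverage = 0.95,
                            br_u_threshold = 5000) {
    r2max <- qchisq(coverage, df = 2)
    n <- nrow(params)
    d2 <- matrix(Inf, n, nrow(model))
    for (j in seq_len(nrow(model))) {
        d2[, j] <- ((params$Br - model$Br[j]) / model$Br_sd[j])^2 +
            ((params$tau_ns - model$tau[j]) / model$tau_sd[j])^2
    }
    lab <- rep(NA_character_, n)
    inside <- d2 <= r2max
    any_in <- rowSums(inside, na.rm = TRUE) > 0
    best <- model$state[max.col(-d2, ties.method = "first")]
    lab[any_in] <- best[any_in]
    if ("U" %in% model$state)
        lab[!is.na(params$Br) & params$Br > br_u_threshold] <- "U"
    lab
}

#' Segment classified groups into levels
#'
#' A level is a maximal run of consecutive groups assigned the same state;
#' unassigned groups break runs. With `censor_transitions = TRUE`, trapping
#' traces that contain more than one distinct state (a rare mid-event
#' transition, plausibly a particle swap) contribute no levels; by default
#' both runs are counted as separate levels.
#'
#' @param labels Character state labels per group (time-ordered; NA =
#'   unassigned).
#' @param t_mean_s Optional group times for level start/end.
#' @param censor_transitions Drop multi-state traces entirely (default
#'   FALSE).
#' @return data.frame: `state`, `start_s`, `end_s`, `n_groups`,
#'   `first_group`, `last_group`.
#' @export
segment_levels <- function(labels, t_mean_s = seq_along(labels),
                           censor_transitions = FALSE) {
    n <- length(labels)
    if (!n) return(data.frame(state = character(), start_s = numeric(),
                              end_s = numeric(), n_groups = integer(),
                              first_group = integer(), last_group = integer()))
    r <- rle(ifelse(is.na(labels), "<NA>", labels))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "<NA>"
    lev <- data.frame(state = r$values[keep],
                      start_s = t_mean_s[starts[keep]],
                      end_s = t_mean_s[ends[keep]],
                      n_groups = r$lengths[keep],
                      first_group = starts[keep],
                      last_group = ends[keep])
    if (censor_transitions && nrow(lev) > 1) {
        # adjacent levels with different states and no unassigned gap between
        # them form a multi-state trace; drop all members of such traces
        drop <- rep(FALSE, nrow(lev))
        for (i in seq_len(nrow(lev) - 1)) {
            contiguous <- lev$first_group[i + 1] == lev$last_group[i] + 1
            if (contiguous && lev$state[i + 1] != lev$state[i])
                drop[c(i, i + 1)] <- TRUE
        }
        lev <- lev[!drop, , drop = FALSE]
    }
    rownames(lev) <- NULL
    lev
}

#' Population fractions per time window with propagated errors
#'
#' Counts levels per time window and reports the quenched-state split
#' `f_Q2 = N_Q2 / (N_Q1 + N_Q2)` and the unquenched fraction
#' `f_U = N_U / (N_Q1 + N_Q2 + N_U)`, each with the binomial standard error
#' `sqrt(f (1 - f) / n)`.
#'
#' @param levels [segment_levels()] output.
#' @param window_s Window width, seconds (default 300 = 5 min data sets).
#' @return data.frame: `window`, `t_start_s`, `N_U`, `N_Q1`, `N_Q2`,
#'   `f_Q2`, `f_Q2_err`, `f_U`, `f_U_err` (NaN-flagged when a window has no
#'   countable levels).
#' @export
population_fractions <- function(levels, window_s = 300) {
    if (!nrow(levels)) stop("no levels: fractions undefined")
    w <- floor(levels$start_s / window_s)
    uw <- sort(unique(w))
    out <- lapply(uw, function(ww) {
        s <- levels$state[w == ww]
        nq1 <- sum(s == "Q1"); nq2 <- sum(s == "Q2"); nu <- sum(s == "U")
        nq <- nq1 + nq2
        f2 <- if (nq > 0) nq2 / nq else NaN
        fu <- if (nq + nu > 0) nu / (nq + nu) else NaN
        data.frame(window = ww, t_start_s = ww * window_s,
                   N_U = nu, N_Q1 = nq1, N_Q2 = nq2,
                   f_Q2 = f2,
                   f_Q2_err = if (nq > 0) sqrt(f2 * (1 - f2) / nq) else NaN,
                   f_U = fu,
                   f_U_err = if (nq + nu > 0) sqrt(fu * (1 - fu) / (nq + nu)) else NaN)
    })
    do.call(rbind, out)
}
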