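#' Constrained hexamer-mixture brightness fit
#'
#' Maximum-likelihood fit of a three-component Gaussian mixture to rod
#' brightness values under the dissociation constraint that the k-hexamer
#' species has mean `k x Br_1Hex` and width `k x sigma_1Hex` (k = 1, 2, 3).
#' Free parameters: `Br_1Hex`, `sigma_1Hex`, and the mixture weights.
#'
#' @param br Brightness values, cts s^-1 uW^-1 (>= 100 required).
#' @param min_n Minimum sample size.
#' @return List of class `pb_hexfit`: `br_1hex`, `br_1hex_err` (Fisher),
#'   `sigma_1hex`, `weights`, `loglik`, `converged`, `flagged`.
#' @export
fit_hexamer_mixture <- function(br, min_n = 100) {
    br <- br[is.finite(br)]
    if (length(br) < min_n)
        stop("need at least ", min_n, " brightness values")
    nll <- function(th) {
        b1 <- exp(th[1]); s1 <- exp(th[2])
        e <- exp(c(th[3], th[4], 0)); w <- e / sum(e)
        if (!is.finite(b1) || !is.finite(s1) || s1 <= 0) return(1e12)
        d <- w[1] * dnorm(br, b1, s1) + w[2] * dnorm(br, 2 * b1, 2 * s1) +
            w[3] * dnorm(br, 3 * b1, 3 * s1)
        if (any(d <= 0)) return(1e12)
        -sum(log(d))
    }
    m <- mean(br); s <- sd(br)
    starts <- list(c(log(m), log(s), 0, 0),
                   c(log(m / 2), log(s / 2), 0, 0),
                   c(log(m / 3), log(s / 3), 0, 0))
    best <- NULL
    for (th0 in starts) {
        op <- tryCatch(optim(th0, nll, method = "BFGS",
                             control = list(maxit = 500, reltol = 1e-12)),
                       error = function(e) NULL)
        if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("mixture fit failed")
    b1 <- exp(best$par[1]); s1 <- exp(best$par[2])
    e <- exp(c(best$par[3], best$par[4], 0)); w <- e / sum(e)
    err <- NA_real_
    flagged <- best$convergence != 0
    H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
    if (!is.null(H)) {
        V <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0) {
            err <- sqrt(V[1, 1]) * b1
        } else flagged <- TRUE
    } else flagged <- TRUE
    structure(list(br_1hex = b1, br_1hex_err = err, sigma_1hex = s1,
                   weights = w, loglik = -best$value,
                   converged = best$convergence == 0, flagged = flagged),
              class = "pb_hexfit")
}

#' Profile log-likelihood of the hexamer mixture over Br_1Hex
#'
#' For each candidate `Br_1Hex` on a grid, maximizes the likelihood over the
#' nuisance parameters (width and weights). Used as a brute-force check that
#' the optimizer found the global maximum.
#'
#' @param br Brightness values.
#' @param grid Candidate `Br_1Hex` values.
#' @return data.frame: `br_1hex`, `loglik`.
#' @export
hexamer_profile_loglik <- function(br, grid) {
    s <- sd(br)
    out <- vapply(grid, function(b1) {
        nll <- function(th) {
            s1 <- exp(th[1]); e <- exp(c(th[2], th[3], 0)); w <- e / sum(e)
            d <- w[1] * dnorm(br, b1, s1) + w[2] * dnorm(br, 2 * b1, 2 * s1) +
                w[3] * dnorm(br, 3 * b1, 3 * s1)
            if (any(d <= 0)) return(1e12)
            -sum(log(d))
        }
        op <- optim(c(log(s / 2), 0, 0), nll, method = "Nelder-Mead",
                    control = list(maxit = 400))
        -op$value
    }, numeric(1))
    data.frame(br_1hex = grid, loglik = out)
}
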