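#' Normalized local scatter density
#'
#' For each point, counts the neighboring points within the axis-aligned box
#' +/- dx by +/- dy (inclusive of the point itself) and normalizes by the
#' maximum count, so the densest point has value 1. Choosing `dx`, `dy`
#' near half the per-dimension standard deviations reproduces the underlying
#' density of a Gaussian cloud with minimal artifacts.
#'
#' @param x,y Point coordinates.
#' @param dx,dy Half-widths of the neighborhood box (defaults `0.5 * sd`).
#' @return Numeric vector of densities in (0, 1], max exactly 1.
#' @export
scatter_density <- function(x, y, dx = 0.5 * sd(x), dy = 0.5 * sd(y)) {
    n <- length(x)
    if (n < 1) stop("need at least one point")
    if (length(y) != n) stop("x and y lengths differ")
    cnt <- integer(n)
    chunk <- max(1L, floor(4e6 / n))
    for (s in seq(1L, n, by = chunk)) {
        e <- min(n, s + chunk - 1L)
        near <- (abs(outer(x[s:e], x, "-")) <= dx) &
            (abs(outer(y[s:e], y, "-")) <= dy)
        cnt[s:e] <- rowSums(near)
    }
    cnt / max(cnt)
}
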