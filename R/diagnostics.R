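#' Geweke convergence diagnostic
#'
#' Compares the mean of the first \code{fracFirst} of an ordered chain with
#' the mean of the last \code{fracLast}:
#' z = (meanA - meanB) / sqrt(sVarA + sVarB), where sVar is a
#' spectral-density-at-zero estimate of the variance of each segment mean
#' (lag-window autocovariance sum with a Bartlett taper over a window of
#' 4\% of the segment length). For a stationary, converged chain z is
#' asymptotically standard normal; |z| > ~2-3 flags a drifting chain.
#'
#' @param chain numeric vector of ordered draws (length >= 100)
#' @param fracFirst,fracLast segment fractions (defaults 0.1 and 0.5)
#' @return the z-score
#' @examples
#' set.seed(1); gewekeZ(rnorm(5000))
#' @export
gewekeZ <- function(chain, fracFirst = 0.1, fracLast = 0.5) {
    chain <- as.numeric(chain)
    m <- length(chain)
    if (m < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
    if (fracFirst <= 0 || fracLast <= 0 || fracFirst + fracLast > 1)
        stop("need fracFirst > 0, fracLast > 0, fracFirst + fracLast <= 1")
    A <- chain[seq_len(floor(fracFirst * m))]
    B <- chain[seq.int(m - floor(fracLast * m) + 1L, m)]
    sv <- function(x) {
        nx <- length(x)
        if (stats::var(x) == 0)
            stop("undefined diagnostic: zero-variance chain segment")
        L <- max(1L, floor(0.04 * nx))
        ac <- stats::acf(x, lag.max = L, type = "covariance",
                         plot = FALSE, demean = TRUE)$acf[, 1, 1]
        w <- 1 - seq_len(L) / (L + 1)             # Bartlett taper
        (ac[1] + 2 * sum(w * ac[-1])) / nx
    }
    (mean(A) - mean(B)) / sqrt(sv(A) + sv(B))
}

#' Sample autocorrelation function of a chain
#'
#' Standard sample autocorrelation normalized by lag 0 (so rho(0) = 1),
#' as used in autocorrelation plots to judge thinning.
#'
#' @param chain numeric vector of ordered draws
#' @param maxLag largest lag (must be < length(chain))
#' @return numeric vector rho(0..maxLag)
#' @export
chainAutocorrelation <- function(chain, maxLag) {
    chain <- as.numeric(chain)
    if (maxLag >= length(chain)) stop("maxLag must be < chain length")
    if (stats::var(chain) == 0) stop("zero-variance chain")
    drop(stats::acf(chain, lag.max = maxLag, plot = FALSE,
                    demean = TRUE)$acf)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, SD, median and equal-tailed 95\% credible
#' interval (2.5th/97.5th percentiles, linear interpolation of order
#' statistics / quantile type 7), plus the Geweke z and lag-1
#' autocorrelation when the chain is long enough to support them.
#'
#' @param draws matrix of draws (rows) by parameters (named columns), or a
#'   \linkS4class{PosteriorDraws} / fitted model
#' @return data.frame with one row per parameter: mean, sd, median, criLow,
#'   criHigh, gewekeZ, lag1Autocorr
#' @examples
#' summarizeDraws(cbind(mu = rnorm(1000), sigma = rexp(1000)))
#' @export
summarizeDraws <- function(draws) {
    if (is(draws, "PosteriorDraws")) draws <- draws@draws
    if (is(draws, "SingleMarkerFit") || is(draws, "CombinedLCMFit"))
        draws <- posteriorDraws(draws)
    draws <- as.matrix(draws)
    if (nrow(draws) < 2) stop("need at least 2 draws to summarize")
    if (is.null(colnames(draws)))
        colnames(draws) <- paste0("par", seq_len(ncol(draws)))
    q <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                 type = 7, names = FALSE))
    gz <- apply(draws, 2, function(x)
        if (length(x) >= 100 && stats::var(x) > 0)
            tryCatch(gewekeZ(x), error = function(e) NA_real_)
        else NA_real_)
    l1 <- apply(draws, 2, function(x)
        if (stats::var(x) > 0) chainAutocorrelation(x, 1L)[2] else NA_real_)
    data.frame(parameter = colnames(draws),
               mean = colMeans(draws),
               sd = apply(draws, 2, stats::sd),
               median = q[, 2], criLow = q[, 1], criHigh = q[, 3],
               gewekeZ = gz, lag1Autocorr = l1,
               row.names = NULL)
}
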