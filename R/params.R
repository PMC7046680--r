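#' Diffuse default priors
#'
#' @param meanLocation,meanVariance normal prior on means and marker-mean
#'   regression coefficients (default N(0, 1e6)).
#' @param varShape,varRate inverse-gamma prior on single-marker variances
#'   (default IG(0.01, 0.01)).
#' @param prevalenceAlpha,prevalenceBeta beta prior on prevalence (default
#'   Beta(1, 1), uniform).
#' @param logisticVariance normal prior variance for logistic coefficients
#'   (default 6.25, i.e. scale 2.5 on standardized covariates, the usual
#'   weakly-informative choice for logistic regression: it spans latent
#'   prevalences from ~0.01 to ~0.99 while preventing the sampler from
#'   locking into the degenerate one-class state through a runaway
#'   intercept).
#' @param wishartScale inverse-Wishart scale for the class covariances
#'   (default \code{NULL}: identity of the right size at fit time).
#' @param wishartDf inverse-Wishart df (default \code{NA}: k + 2 at fit
#'   time).
#' @return a \linkS4class{PriorSpec}
#' @export
priorSpec <- function(meanLocation = 0, meanVariance = 1e6,
                      varShape = 0.01, varRate = 0.01,
                      prevalenceAlpha = 1, prevalenceBeta = 1,
                      logisticVariance = 6.25,
                      wishartScale = NULL, wishartDf = NA_real_) {
    new("PriorSpec", meanLocation = meanLocation, meanVariance = meanVariance,
        varShape = varShape, varRate = varRate,
        prevalenceAlpha = prevalenceAlpha, prevalenceBeta = prevalenceBeta,
        logisticVariance = logisticVariance,
        wishartScale = wishartScale, wishartDf = wishartDf)
}

#' MCMC settings
#'
#' Defaults reproduce the single-marker run length used throughout: one
#' chain of 20,000 iterations, 8,000 burn-in, keep every 25th draw (480
#' retained draws). \code{combinedMCMCSettings()} gives the longer run used
#' for the multivariate model (35,000 / 17,000 / 45; 400 draws).
#'
#' @param nIterations,burnIn,thin,nChains,seed see
#'   \linkS4class{MCMCSettings}
#' @return an \linkS4class{MCMCSettings}
#' @export
mcmcSettings <- function(nIterations = 20000L, burnIn = 8000L, thin = 25L,
                         nChains = 1L, seed = 1L) {
    s <- new("MCMCSettings", nIterations = as.integer(nIterations),
             burnIn = as.integer(burnIn), thin = as.integer(thin),
             nChains = as.integer(nChains), seed = as.integer(seed))
    if (retainedDrawCount(s) < 100L)
        warning("fewer than 100 retained draws; posterior summaries will be noisy")
    s
}

#' @rdname mcmcSettings
#' @export
combinedMCMCSettings <- function(nIterations = 35000L, burnIn = 17000L,
                                 thin = 45L, nChains = 1L, seed = 1L)
    mcmcSettings(nIterations, burnIn, thin, nChains, seed)

#' Number of retained draws implied by MCMC settings
#'
#' nChains * floor((nIterations - burnIn) / thin).
#'
#' @param settings an \linkS4class{MCMCSettings}
#' @return integer draw count
#' @export
retainedDrawCount <- function(settings)
    settings@nChains *
        ((settings@nIterations - settings@burnIn) %/% settings@thin)
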