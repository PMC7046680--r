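#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<-
NULL

#' MarkerCohort: subjects with continuous diagnostic markers and covariates
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one column
#' per subject. The single assay \code{"markers"} is a k x n matrix of
#' continuous marker values (rows are markers, e.g. \code{LDH}, \code{UA},
#' \code{Cr}); \code{colData} carries the covariates and, for synthetic
#' cohorts, the true latent disease label in column \code{.trueLabel}.
#'
#' Use \code{\link{markerMatrix}} to obtain the transposed (n x k) matrix
#' that the model-fitting functions consume, \code{\link{covariateTable}}
#' for the covariates, and \code{\link{trueLabels}} for the labels (or
#' \code{NULL} when absent).
#'
#' @slot covariateNames character vector naming which colData columns are
#'   modelling covariates (the rest are bookkeeping).
#' @export
setClass("MarkerCohort",
    contains = "SummarizedExperiment",
    slots = c(covariateNames = "character"))

setValidity("MarkerCohort", function(object) {
    msg <- character()
    if (!"markers" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'markers' is required")
    else {
        m <- assay(object, "markers")
        if (!is.numeric(m))
            msg <- c(msg, "marker assay must be numeric")
    }
    missing <- setdiff(object@covariateNames, colnames(colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("covariate columns absent from colData: ",
                             paste(missing, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Prior specification for the latent class models
#'
#' Diffuse conjugate priors used by both samplers: normal priors on all
#' class-conditional means and regression coefficients, inverse-gamma on the
#' single-marker variances, beta on prevalence, normal on the logistic
#' coefficients (tighter, to keep the logistic step away from separation
#' blow-up), and inverse-Wishart on the class-conditional covariance
#' matrices (scale matrix defaults to the identity, df to k + 2 at fit time
#' when \code{wishartDf} is \code{NA}).
#'
#' @slot meanLocation,meanVariance normal hyperparameters for means/betas.
#' @slot varShape,varRate inverse-gamma hyperparameters for variances.
#' @slot prevalenceAlpha,prevalenceBeta beta hyperparameters for prevalence.
#' @slot logisticVariance normal prior variance for logistic coefficients.
#' @slot wishartScale matrix or NULL (identity at fit time).
#' @slot wishartDf inverse-Wishart degrees of freedom (NA: k + 2 at fit time).
#' @export
setClass("PriorSpec", slots = c(
    meanLocation = "numeric", meanVariance = "numeric",
    varShape = "numeric", varRate = "numeric",
    prevalenceAlpha = "numeric", prevalenceBeta = "numeric",
    logisticVariance = "numeric",
    wishartScale = "ANY", wishartDf = "numeric"))

setValidity("PriorSpec", function(object) {
    msg <- character()
    if (object@meanVariance <= 0) msg <- c(msg, "meanVariance must be > 0")
    if (object@varShape <= 0 || object@varRate <= 0)
        msg <- c(msg, "inverse-gamma hyperparameters must be > 0")
    if (object@prevalenceAlpha <= 0 || object@prevalenceBeta <= 0)
        msg <- c(msg, "beta hyperparameters must be > 0")
    if (object@logisticVariance <= 0)
        msg <- c(msg, "logisticVariance must be > 0")
    if (length(msg)) msg else TRUE
})

#' MCMC settings for the latent class samplers
#'
#' @slot nIterations total iterations per chain.
#' @slot burnIn iterations discarded from the start of each chain.
#' @slot thin keep every thin-th post-burn-in draw (the "lag").
#' @slot nChains number of independent chains.
#' @slot seed integer seed.
#' @export
setClass("MCMCSettings", slots = c(
    nIterations = "integer", burnIn = "integer", thin = "integer",
    nChains = "integer", seed = "integer"))

setValidity("MCMCSettings", function(object) {
    msg <- character()
    if (object@nIterations < 1) msg <- c(msg, "nIterations must be >= 1")
    if (object@burnIn < 0 || object@burnIn >= object@nIterations)
        msg <- c(msg, "burnIn must satisfy 0 <= burnIn < nIterations")
    if (object@thin < 1) msg <- c(msg, "thin must be >= 1")
    if (object@nChains < 1) msg <- c(msg, "nChains must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Posterior draws from a fitted latent class model
#'
#' @slot draws m x q numeric matrix of retained draws with named columns.
#' @slot settings the \linkS4class{MCMCSettings} that produced the draws.
#' @slot priors the \linkS4class{PriorSpec} used.
#' @export
setClass("PosteriorDraws", slots = c(
    draws = "matrix", settings = "MCMCSettings", priors = "PriorSpec"))

setValidity("PosteriorDraws", function(object) {
    expected <- object@settings@nChains *
        ((object@settings@nIterations - object@settings@burnIn) %/%
             object@settings@thin)
    if (nrow(object@draws) != expected)
        return(sprintf("draw count %d != nChains * floor((nIterations - burnIn)/thin) = %d",
                       nrow(object@draws), expected))
    if (is.null(colnames(object@draws)))
        return("draws must have named columns")
    TRUE
})

#' Fitted single-marker latent class model
#'
#' Columns of the draws matrix: \code{pi}, \code{muPos}, \code{muNeg},
#' \code{varPos}, \code{varNeg}. Every retained draw satisfies the
#' identifiability anchor muPos > muNeg.
#'
#' @slot posterior a \linkS4class{PosteriorDraws}.
#' @slot classProb posterior P(D = 1 | y) per subject.
#' @slot y the data the model was fitted to.
#' @export
setClass("SingleMarkerFit", slots = c(
    posterior = "PosteriorDraws", classProb = "numeric", y = "numeric"))

setValidity("SingleMarkerFit", function(object) {
    d <- object@posterior@draws
    msg <- character()
    if (!all(c("pi", "muPos", "muNeg", "varPos", "varNeg") %in% colnames(d)))
        msg <- c(msg, "draws must contain pi, muPos, muNeg, varPos, varNeg")
    else if (any(d[, "muPos"] <= d[, "muNeg"]))
        msg <- c(msg, "anchor constraint muPos > muNeg violated in draws")
    if (any(object@classProb < 0 | object@classProb > 1))
        msg <- c(msg, "classProb must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Fitted covariate-adjusted multivariate latent class model
#'
#' The draws matrix flattens, per retained draw, the marker-mean coefficient
#' matrix B (columns \code{beta.<marker>.<term>}), the logistic coefficients
#' (\code{alpha.<term>}) and the lower triangles of the class-conditional
#' covariances (\code{sigma0.<i>.<j>}, \code{sigma1.<i>.<j>}).
#'
#' @slot posterior a \linkS4class{PosteriorDraws}.
#' @slot classProb posterior P(D = 1 | Y, x) per subject.
#' @slot markers marker (column) names of Y.
#' @slot terms names of the covariate design columns (without intercept).
#' @slot anchor marker whose disease effect is constrained positive.
#' @slot transform centring/scaling applied to the covariates before fitting.
#' @export
setClass("CombinedLCMFit", slots = c(
    posterior = "PosteriorDraws", classProb = "numeric",
    markers = "character", terms = "character", anchor = "character",
    transform = "list"))

#' @describeIn MarkerCohort compact display
#' @param object a MarkerCohort
#' @export
setMethod("show", "MarkerCohort", function(object) {
    cat(sprintf("MarkerCohort: %d subjects, %d markers (%s)\n",
                ncol(object), nrow(object),
                paste(rownames(object), collapse = ", ")))
    if (length(object@covariateNames))
        cat("covariates:", paste(object@covariateNames, collapse = ", "), "\n")
    if (".trueLabel" %in% colnames(colData(object)))
        cat(sprintf("true latent labels present (prevalence %.3f)\n",
                    mean(colData(object)$.trueLabel)))
    excl <- metadata(object)$exclusions
    if (!is.null(excl) && nrow(excl))
        cat(sprintf("%d subjects excluded during preprocessing\n", nrow(excl)))
    invisible(object)
})

setMethod("show", "PosteriorDraws", function(object) {
    cat(sprintf("PosteriorDraws: %d draws x %d parameters\n",
                nrow(object@draws), ncol(object@draws)))
    invisible(object)
})

setMethod("show", "SingleMarkerFit", function(object) {
    cat(sprintf("SingleMarkerFit: n = %d subjects, %d retained draws\n",
                length(object@y), nrow(object@posterior@draws)))
    s <- colMeans(object@posterior@draws)
    cat(sprintf("posterior means: pi %.3f, muPos %.3f, muNeg %.3f\n",
                s["pi"], s["muPos"], s["muNeg"]))
    invisible(object)
})

setMethod("show", "CombinedLCMFit", function(object) {
    cat(sprintf("CombinedLCMFit: %d markers (%s), %d subjects, %d draws\n",
                length(object@markers),
                paste(object@markers, collapse = ", "),
                length(object@classProb), nrow(object@posterior@draws)))
    cat(sprintf("anchor marker: %s; covariate terms: %s\n", object@anchor,
                if (length(object@terms)) paste(object@terms, collapse = ", ")
                else "(none)"))
    invisible(object)
})
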