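#' Marker matrix of a cohort (subjects x markers)
#'
#' @param x a \linkS4class{MarkerCohort}
#' @return numeric matrix, one row per subject, one column per marker
#' @export
setGeneric("markerMatrix", function(x) standardGeneric("markerMatrix"))

#' Covariate table of a cohort
#'
#' @param x a \linkS4class{MarkerCohort}
#' @return a \code{DataFrame} of the declared modelling covariates
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))

#' True latent labels of a (synthetic) cohort
#'
#' @param x a \linkS4class{MarkerCohort}
#' @return integer vector in \{0, 1\}, or \code{NULL} when no truth is known
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' Subject identifiers
#'
#' @param x a \linkS4class{MarkerCohort}
#' @return character vector of subject ids
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Retained posterior draws of a fit as a matrix
#'
#' @param x a fitted model or \linkS4class{PosteriorDraws}
#' @return numeric matrix, one row per retained draw, named columns
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Posterior class-membership probabilities P(D = 1 | data)
#'
#' @param x a fitted latent class model
#' @param ... further arguments for methods
#' @return numeric vector in [0, 1], one entry per subject
#' @export
setGeneric("classProbabilities",
    function(x, ...) standardGeneric("classProbabilities"))

#' @rdname markerMatrix
setMethod("markerMatrix", "MarkerCohort", function(x) t(assay(x, "markers")))

#' @rdname covariateTable
setMethod("covariateTable", "MarkerCohort", function(x)
    colData(x)[, x@covariateNames, drop = FALSE])

#' @rdname trueLabels
setMethod("trueLabels", "MarkerCohort", function(x) {
    cd <- colData(x)
    if (".trueLabel" %in% colnames(cd)) as.integer(cd$.trueLabel) else NULL
})

#' @rdname subjectIds
setMethod("subjectIds", "MarkerCohort", function(x) colnames(x))

#' @rdname posteriorDraws
setMethod("posteriorDraws", "PosteriorDraws", function(x) x@draws)
#' @rdname posteriorDraws
setMethod("posteriorDraws", "SingleMarkerFit", function(x) x@posterior@draws)
#' @rdname posteriorDraws
setMethod("posteriorDraws", "CombinedLCMFit", function(x) x@posterior@draws)

#' @rdname classProbabilities
setMethod("classProbabilities", "SingleMarkerFit", function(x, ...) x@classProb)
#' @rdname classProbabilities
setMethod("classProbabilities", "CombinedLCMFit", function(x, ...) x@classProb)
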