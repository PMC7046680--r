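#' Binormal sensitivity, specificity and AUC
#'
#' Under class-conditional normal marker distributions
#' Y | D=1 ~ N(muPos, varPos), Y | D=0 ~ N(muNeg, varNeg), a subject is
#' called positive when Y exceeds the cut-off c, giving
#' sensitivity = P(Y > c | D=1) = 1 - Phi((c - muPos)/sqrt(varPos)),
#' specificity = P(Y <= c | D=0) = Phi((c - muNeg)/sqrt(varNeg)), and
#' AUC = P(Y+ > Y-) = Phi((muPos - muNeg)/sqrt(varPos + varNeg)).
#'
#' @param c cut-off on the marker scale (vectorized)
#' @param muPos,varPos diseased-class mean and variance
#' @param muNeg,varNeg non-diseased-class mean and variance
#' @return probability (vector)
#' @examples
#' binormalSensitivity(0, muPos = 1, varPos = 1)   # P(N(1,1) > 0)
#' binormalAUC(2, 1, 0, 1)                         # Phi(2/sqrt(2))
#' @export
binormalSensitivity <- function(c, muPos, varPos) {
    if (any(varPos <= 0)) stop("varPos must be > 0")
    1 - stats::pnorm((c - muPos) / sqrt(varPos))
}

#' @rdname binormalSensitivity
#' @export
binormalSpecificity <- function(c, muNeg, varNeg) {
    if (any(varNeg <= 0)) stop("varNeg must be > 0")
    stats::pnorm((c - muNeg) / sqrt(varNeg))
}

#' @rdname binormalSensitivity
#' @export
binormalAUC <- function(muPos, varPos, muNeg, varNeg) {
    if (any(varPos <= 0) || any(varNeg <= 0)) stop("variances must be > 0")
    stats::pnorm((muPos - muNeg) / sqrt(varPos + varNeg))
}

.cutoffGrid <- function(muPos, varPos, muNeg, varNeg, gridSize) {
    s <- sqrt(max(varPos, varNeg))
    seq(min(muPos, muNeg) - 4 * s, max(muPos, muNeg) + 4 * s,
        length.out = gridSize)
}

#' Youden-optimal cut-off for a binormal marker
#'
#' Maximizes J(c) = sensitivity(c) + specificity(c) - 1 over a grid spanning
#' [min(mu) - 4 sigma_max, max(mu) + 4 sigma_max]. Ties are broken towards
#' the smallest cut-off.
#'
#' @inheritParams binormalSensitivity
#' @param gridSize number of grid points (default 1001)
#' @param grid optional explicit cut-off grid (overrides gridSize)
#' @return list with \code{cutoff}, \code{J}, \code{sensitivity},
#'   \code{specificity} at the optimum
#' @examples
#' youdenCutoff(1, 1, -1, 1)$cutoff   # symmetric: ~0
#' @export
youdenCutoff <- function(muPos, varPos, muNeg, varNeg, gridSize = 1001L,
                         grid = NULL) {
    if (is.null(grid))
        grid <- .cutoffGrid(muPos, varPos, muNeg, varNeg, gridSize)
    if (!length(grid)) stop("empty cut-off grid")
    J <- binormalSensitivity(grid, muPos, varPos) +
        binormalSpecificity(grid, muNeg, varNeg) - 1
    i <- which.max(J)   # which.max returns the first (smallest) maximizer
    list(cutoff = grid[i], J = J[i],
         sensitivity = binormalSensitivity(grid[i], muPos, varPos),
         specificity = binormalSpecificity(grid[i], muNeg, varNeg))
}

#' Binormal ROC curve over a cut-off grid
#'
#' Evaluates (1 - specificity, sensitivity) across the grid, ordered so the
#' curve runs from (0,0) to (1,1).
#'
#' @inheritParams youdenCutoff
#' @return data.frame with columns \code{cutoff}, \code{fpr}, \code{tpr}
#' @export
rocCurve <- function(muPos, varPos, muNeg, varNeg, gridSize = 1001L,
                     grid = NULL) {
    if (is.null(grid))
        grid <- .cutoffGrid(muPos, varPos, muNeg, varNeg, gridSize)
    if (!length(grid)) stop("empty cut-off grid")
    grid <- sort(grid, decreasing = TRUE)   # high cut-off = (0,0) corner
    data.frame(cutoff = grid,
               fpr = 1 - binormalSpecificity(grid, muNeg, varNeg),
               tpr = binormalSensitivity(grid, muPos, varPos))
}

#' Distributional separation Delta = 1 - overlap
#'
#' Measures how little the diseased and non-diseased marker densities
#' overlap: Delta = 1 - OVL with OVL = integral of min(f+, f-), computed by
#' adaptive quadrature over [min(mu) - 8 sigma_max, max(mu) + 8 sigma_max]
#' (absolute tolerance 1e-6). Delta = 0 for identical components and tends
#' to 1 as the classes separate, so better markers score higher.
#'
#' @inheritParams binormalSensitivity
#' @return Delta in [0, 1]
#' @examples
#' separationDelta(2, 1, 0, 1)  # equal variances: 1 - 2*pnorm(-1)
#' @export
separationDelta <- function(muPos, varPos, muNeg, varNeg) {
    if (varPos <= 0 || varNeg <= 0) stop("variances must be > 0")
    s <- sqrt(max(varPos, varNeg))
    lo <- min(muPos, muNeg) - 8 * s
    hi <- max(muPos, muNeg) + 8 * s
    ovl <- stats::integrate(function(y)
        pmin(stats::dnorm(y, muPos, sqrt(varPos)),
             stats::dnorm(y, muNeg, sqrt(varNeg))),
        lo, hi, abs.tol = 1e-6)$value
    min(max(1 - ovl, 0), 1)
}

#' AUC-optimal linear combination weights for correlated markers
#'
#' For k jointly normal markers with class-conditional mean difference
#' Delta(x) = mu(x,1) - mu(x,0) and covariances Sigma1, Sigma0, the linear
#' composite a'Y with a = (Sigma0 + Sigma1)^-1 Delta(x) maximizes the
#' combined AUC. Solved as a linear system (no explicit inverse).
#'
#' @param muPos,muNeg k-vectors of class-conditional means at the covariate
#'   profile of interest
#' @param sigma0,sigma1 k x k class-conditional covariance matrices
#' @return list with weights \code{a}, mean difference \code{delta}, and the
#'   means the weights were evaluated at
#' @examples
#' combinationWeights(c(1, 0), c(0, 0), diag(2), diag(2))$a  # (0.5, 0)
#' @export
combinationWeights <- function(muPos, muNeg, sigma0, sigma1) {
    delta <- muPos - muNeg
    S <- as.matrix(sigma0) + as.matrix(sigma1)
    if (nrow(S) != length(delta)) stop("dimension mismatch")
    a <- tryCatch(drop(solve(S, delta)),
                  error = function(e)
                      stop("Sigma0 + Sigma1 is numerically singular: ",
                           conditionMessage(e)))
    list(a = a, delta = delta, muPos = muPos, muNeg = muNeg)
}

#' Accuracy of the optimal linear marker combination
#'
#' Given weights a (from \code{\link{combinationWeights}}), the composite
#' score a'Y is itself binormal with means a'mu(x,d) and variances
#' a'Sigma_d a, so
#' cSens = Phi((a'mu(x,1) - c*) / sqrt(a'Sigma1 a)),
#' cSpec = Phi((c* - a'mu(x,0)) / sqrt(a'Sigma0 a)), and
#' cAUC = Phi(sqrt(a'Delta(x))). When \code{cutoff} is NULL the Youden
#' cut-off on the composite scale is used (a single c* serves as both the
#' positive and negative threshold).
#'
#' @param weights result of \code{\link{combinationWeights}}
#' @param sigma0,sigma1 class-conditional covariances
#' @param cutoff composite-scale cut-off c*; NULL = Youden-optimal
#' @param gridSize grid resolution for the Youden search
#' @return list with \code{cutoff}, \code{cSensitivity}, \code{cSpecificity},
#'   \code{cAUC}
#' @export
combinedAccuracy <- function(weights, sigma0, sigma1, cutoff = NULL,
                             gridSize = 1001L) {
    a <- weights$a
    aDelta <- sum(a * weights$delta)
    if (aDelta < -1e-8)
        stop("a'Delta negative: Sigma0 + Sigma1 numerically singular or weights inconsistent")
    aDelta <- max(aDelta, 0)
    mPos <- sum(a * weights$muPos)
    mNeg <- sum(a * weights$muNeg)
    v1 <- drop(a %*% as.matrix(sigma1) %*% a)
    v0 <- drop(a %*% as.matrix(sigma0) %*% a)
    if (v1 <= 0 || v0 <= 0) {
        # zero weights (no separation): the composite is degenerate
        return(list(cutoff = NA_real_, cSensitivity = NA_real_,
                    cSpecificity = NA_real_, cAUC = stats::pnorm(sqrt(aDelta))))
    }
    if (is.null(cutoff))
        cutoff <- youdenCutoff(mPos, v1, mNeg, v0, gridSize)$cutoff
    list(cutoff = cutoff,
         cSensitivity = binormalSensitivity(cutoff, mPos, v1),
         cSpecificity = binormalSpecificity(cutoff, mNeg, v0),
         cAUC = stats::pnorm(sqrt(aDelta)))
}

#' Combined ROC curve of the optimal composite
#'
#' @inheritParams combinedAccuracy
#' @param gridSize grid resolution
#' @return data.frame with columns \code{cutoff}, \code{fpr}, \code{tpr}
#' @export
combinedRocCurve <- function(weights, sigma0, sigma1, gridSize = 1001L) {
    a <- weights$a
    rocCurve(sum(a * weights$muPos), drop(a %*% as.matrix(sigma1) %*% a),
             sum(a * weights$muNeg), drop(a %*% as.matrix(sigma0) %*% a),
             gridSize = gridSize)
}
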