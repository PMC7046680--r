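#' Marker mean structure of the covariate-adjusted latent class model
#'
#' For marker k the class-conditional mean is
#' mu_k(x, d) = beta0 + betaX' x + betaD d + betaXD' (x d): covariates shift
#' both classes, the disease indicator shifts the diseased class, and the
#' interaction lets covariate effects differ by class.
#'
#' @param beta coefficient vector (single marker) ordered
#'   (beta0, betaX, betaD, betaXD), or a matrix with one column per marker
#' @param x encoded covariate vector (length p; may be length 0)
#' @param d disease indicator, 0 or 1
#' @return scalar mean (or k-vector for a coefficient matrix)
#' @examples
#' meanStructure(c(1, 2, 3, -1), x = 0.5, d = 1)  # 1 + 1 + 3 - 0.5 = 4.5
#' @export
meanStructure <- function(beta, x, d) {
    stopifnot(d %in% c(0, 1))
    x <- as.numeric(x); p <- length(x)
    w <- c(1, x, d, x * d)
    beta <- if (is.matrix(beta)) beta else matrix(beta)
    if (nrow(beta) != 2 * (p + 1))
        stop("dimension mismatch: need 2(p+1) coefficients per marker")
    drop(crossprod(beta, w))
}

#' Covariate-dependent disease probability
#'
#' Logistic model for the latent prevalence:
#' logit P(D = 1 | x) = alpha0 + alpha' x.
#'
#' @param alpha coefficient vector (alpha0, alpha1..alphap)
#' @param x encoded covariate vector (length p)
#' @return probability in (0, 1)
#' @examples
#' diseaseProbability(c(qlogis(0.457)), numeric(0))  # 0.457
#' @export
diseaseProbability <- function(alpha, x) {
    x <- as.numeric(x)
    if (length(alpha) != length(x) + 1) stop("dimension mismatch")
    stats::plogis(alpha[1] + sum(alpha[-1] * x))
}

.betaTermNames <- function(covNames)
    c("(Intercept)", covNames, "D",
      if (length(covNames)) paste0(covNames, ":D"))

.lowerTriNames <- function(prefix, k) {
    idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    sprintf("%s.%d.%d", prefix, idx[, 1], idx[, 2])
}

#' Fit the covariate-adjusted multivariate latent class model
#'
#' Joint model for k correlated continuous markers with latent disease
#' status and covariates acting on both the marker means and the
#' prevalence:
#' D_i | x_i ~ Bernoulli(plogis(alpha0 + alpha' x_i)),
#' Y_i | x_i, D_i ~ MVN(mu(x_i, D_i), Sigma_{D_i}), with per-marker means
#' as in \code{\link{meanStructure}}.
#'
#' Sampling is Metropolis-within-Gibbs: latent labels from their full
#' conditional; all mean-structure coefficients jointly from their Gaussian
#' full conditional (the two classes contribute
#' Sigma_d^{-1} (x) W_d'W_d precision blocks); class covariances from
#' conjugate inverse-Wishart updates; the logistic coefficients by an
#' adaptive random-walk Metropolis step (step size tuned towards 30\%
#' acceptance during burn-in, frozen afterwards). Label switching is
#' resolved by re-labelling draws so the anchor marker's disease effect is
#' positive (classes, covariances and logistic signs transformed
#' consistently).
#'
#' @param Y n x k numeric matrix of marker values, named columns
#' @param X n x p encoded covariate matrix (e.g. from
#'   \code{\link{encodeCovariates}}); may have zero columns
#' @param priors a \linkS4class{PriorSpec}; governs the logistic and
#'   covariance priors, and the mean-structure prior when
#'   \code{priorScale = "fixed"}
#' @param settings an \linkS4class{MCMCSettings}
#' @param anchor marker name (or index) whose disease effect betaD is
#'   constrained positive; defaults to \code{"Cr"} when present, else the
#'   first marker
#' @param includeInteractions include covariate-by-disease interaction terms
#'   in every marker mean (default TRUE)
#' @param priorScale \code{"data"} (default): weakly-informative
#'   data-envelope priors on the mean-structure coefficients — for marker k
#'   the intercept prior is N(mean(Y_k), (3 sd(Y_k))^2) and every other
#'   coefficient N(0, (3 sd(Y_k))^2). This keeps the parameters of a
#'   momentarily empty latent class inside the data envelope, so the chain
#'   escapes the collapsed (single-class) region instead of being absorbed
#'   by it — the standard data-dependent-prior stabilisation for mixture
#'   MCMC. \code{"fixed"}: N(meanLocation, meanVariance) from \code{priors}
#'   on every coefficient.
#' @return a \linkS4class{CombinedLCMFit}
#' @export
fitCombinedLCM <- function(Y, X = NULL,
                           priors = priorSpec(meanVariance = 100),
                           settings = combinedMCMCSettings(),
                           anchor = NULL, includeInteractions = TRUE,
                           priorScale = c("data", "fixed")) {
    priorScale <- match.arg(priorScale)
    stopifnot(is(priors, "PriorSpec"), is(settings, "MCMCSettings"))
    Y <- as.matrix(Y)
    if (is.null(colnames(Y)))
        colnames(Y) <- paste0("M", seq_len(ncol(Y)))
    n <- nrow(Y); k <- ncol(Y)
    if (k < 2) stop("the multivariate model needs k >= 2 markers")
    if (is.null(X)) X <- matrix(numeric(0), n, 0)
    X <- as.matrix(X)
    if (nrow(X) != n) stop("dimension error: X and Y row counts differ")
    if (any(!is.finite(Y)) || (ncol(X) && any(!is.finite(X))))
        stop("non-finite values in Y or X")
    p <- ncol(X)
    covNames <- if (p) { if (is.null(colnames(X)))
        paste0("x", seq_len(p)) else colnames(X) } else character()
    colnames(X) <- covNames
    if (is.null(anchor))
        anchor <- if ("Cr" %in% colnames(Y)) "Cr" else colnames(Y)[1]
    if (is.numeric(anchor)) anchor <- colnames(Y)[anchor]
    aIdx <- match(anchor, colnames(Y))
    if (is.na(aIdx)) stop("anchor marker '", anchor, "' not among markers")

    useInt <- includeInteractions && p > 0
    # Internal parameterization: class-specific coefficient blocks, so the
    # label-switch move (swap classes) maps the prior onto itself exactly.
    # With interactions each class has its own intercept + slopes
    # (G rows: g0int, g0 slopes, g1int, g1 slopes); without, the slopes are
    # shared (G rows: a0, a1, shared slopes). The reported draws are
    # converted to the (beta0, betaX, betaD, betaXD) convention.
    if (useInt) {
        qw <- 2L * (p + 1L)
        W0base <- cbind(1, X, 0, 0 * X)
        W1base <- cbind(0, 0 * X, 1, X)
        i0blk <- seq_len(p + 1L); i1blk <- p + 1L + i0blk
    } else {
        qw <- p + 2L
        W0base <- cbind(1, 0, X)
        W1base <- cbind(0, 1, X)
    }
    terms <- .betaTermNames(covNames)

    # per-coefficient prior (intercepts centred on the marker, slopes on 0)
    ybar <- colMeans(Y); sdY <- apply(Y, 2, stats::sd)
    intRows <- if (useInt) c(1L, p + 2L) else c(1L, 2L)
    if (priorScale == "data") {
        priorVar <- rep((3 * sdY)^2, each = qw)
        priorMean <- as.vector(vapply(seq_len(k), function(j) {
            mj <- numeric(qw); mj[intRows] <- ybar[j]; mj
        }, numeric(qw)))
    } else {
        priorVar <- rep(priors@meanVariance, k * qw)
        priorMean <- rep(priors@meanLocation, k * qw)
    }
    tauA <- priors@logisticVariance
    nu0 <- if (is.na(priors@wishartDf)) k + 2 else priors@wishartDf
    # default inverse-Wishart scale matched to the marker scales (with
    # df = k + 2 the prior mean of Sigma is then diag(var(Y_k))); an
    # identity scale would badly distort markers far from unit variance
    Psi0 <- if (!is.null(priors@wishartScale)) as.matrix(priors@wishartScale)
            else if (priorScale == "data") diag(sdY^2, k)
            else diag(k)

    nKeep <- (settings@nIterations - settings@burnIn) %/% settings@thin
    betaNames <- as.vector(vapply(colnames(Y), function(m)
        paste("beta", m, terms, sep = "."), character(length(terms))))
    alphaNames <- paste0("alpha.", c("(Intercept)", covNames))
    parNames <- c(betaNames, alphaNames,
                  .lowerTriNames("sigma0", k), .lowerTriNames("sigma1", k))
    draws <- matrix(NA_real_, settings@nChains * nKeep, length(parNames),
                    dimnames = list(NULL, parNames))
    probSum <- numeric(n)
    ltri <- lower.tri(diag(k), diag = TRUE)

    set.seed(settings@seed)
    for (chain in seq_len(settings@nChains)) {
        km <- stats::kmeans(scale(Y), centers = 2L, nstart = 5L)
        d <- as.integer(km$cluster == which.max(km$centers[, aIdx]))
        if (sum(d) %in% c(0L, n)) d <- as.integer(Y[, aIdx] >
                                                  stats::median(Y[, aIdx]))
        # OLS warm start for the class-block coefficient matrix
        Wd <- W0base
        Wd[d == 1L, ] <- W1base[d == 1L, ]
        B <- tryCatch(qr.solve(Wd, Y), error = function(e) {
            Binit <- matrix(0, qw, k)
            Binit[intRows, ] <- rep(ybar, each = 2)
            Binit
        })
        if (!is.matrix(B) || nrow(B) != qw) B <- matrix(B, qw, k)
        res <- Y - Wd %*% B
        S <- .sym(crossprod(res) / max(n - qw, k + 1))
        Sig0 <- Sig1 <- S + diag(1e-6, k)
        alpha <- c(.logit(min(max(mean(d), 0.05), 0.95)), rep(0, p))
        mhScale <- 0.5; mhAcc <- 0
        row <- (chain - 1L) * nKeep

        for (it in seq_len(settings@nIterations)) {
            # latent labels
            eta <- drop(cbind(1, X) %*% alpha)
            mu0 <- W0base %*% B
            mu1 <- W1base %*% B
            lp1 <- stats::plogis(eta, log.p = TRUE) +
                .dmvnormLog(Y, mu1, Sig1)
            lp0 <- stats::plogis(-eta, log.p = TRUE) +
                .dmvnormLog(Y, mu0, Sig0)
            pd <- 1 / (1 + exp(lp0 - lp1))
            d <- stats::rbinom(n, 1L, pd)
            i1 <- d == 1L

            # mean-structure coefficients (joint Gaussian full conditional)
            W0 <- W0base[!i1, , drop = FALSE]
            W1 <- W1base[i1, , drop = FALSE]
            S0inv <- chol2inv(chol(Sig0)); S1inv <- chol2inv(chol(Sig1))
            P <- kronecker(S0inv, crossprod(W0)) +
                 kronecker(S1inv, crossprod(W1)) +
                 diag(1 / priorVar, k * qw)
            l <- as.vector(crossprod(W0, Y[!i1, , drop = FALSE]) %*% S0inv +
                           crossprod(W1, Y[i1, , drop = FALSE]) %*% S1inv) +
                 priorMean / priorVar
            R <- chol(.sym(P))
            mth <- backsolve(R, backsolve(R, l, transpose = TRUE))
            theta <- mth + backsolve(R, stats::rnorm(k * qw))
            B <- matrix(theta, qw, k)

            # class covariances
            r0 <- Y[!i1, , drop = FALSE] - W0 %*% B
            r1 <- Y[i1, , drop = FALSE] - W1 %*% B
            Sig0 <- .sym(.rinvwishart(nu0 + nrow(r0),
                                      .sym(Psi0 + crossprod(r0))))
            Sig1 <- .sym(.rinvwishart(nu0 + nrow(r1),
                                      .sym(Psi0 + crossprod(r1))))

            # logistic coefficients: adaptive random-walk Metropolis
            prop <- alpha + mhScale * stats::rnorm(p + 1)
            etaP <- drop(cbind(1, X) %*% prop)
            log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
            llNow <- sum(d * eta - log1pexp(eta)) -
                sum(alpha^2) / (2 * tauA)
            llProp <- sum(d * etaP - log1pexp(etaP)) -
                sum(prop^2) / (2 * tauA)
            if (log(stats::runif(1)) < llProp - llNow) {
                alpha <- prop; mhAcc <- mhAcc + 1
            }
            if (it <= settings@burnIn && it %% 50L == 0L) {
                rate <- mhAcc / 50
                mhScale <- mhScale * exp(rate - 0.3)
                mhAcc <- 0
            }

            # anchor: disease effect on the anchor marker must be positive;
            # swapping the class blocks is an exact symmetry of the
            # unconstrained posterior (exchangeable priors by construction)
            if (B[intRows[2], aIdx] - B[intRows[1], aIdx] < 0) {
                if (useInt) B <- B[c(i1blk, i0blk), , drop = FALSE]
                else B[c(1L, 2L), ] <- B[c(2L, 1L), ]
                tmp <- Sig0; Sig0 <- Sig1; Sig1 <- tmp
                alpha <- -alpha
                d <- 1L - d
            }

            if (it > settings@burnIn &&
                (it - settings@burnIn) %% settings@thin == 0L) {
                row <- row + 1L
                # convert class blocks to (beta0, betaX, betaD, betaXD)
                Bout <- if (useInt)
                    rbind(B[i0blk, , drop = FALSE],
                          B[i1blk, , drop = FALSE] - B[i0blk, , drop = FALSE])
                else rbind(B[1, ],
                           if (p) B[seq_len(p) + 2L, , drop = FALSE],
                           B[2, ] - B[1, ],
                           if (p) matrix(0, p, k))
                draws[row, ] <- c(as.vector(Bout), alpha,
                                  Sig0[ltri], Sig1[ltri])
                # per-draw allocation with the current (relabelled) state
                eta <- drop(cbind(1, X) %*% alpha)
                lp1 <- stats::plogis(eta, log.p = TRUE) +
                    .dmvnormLog(Y, W1base %*% B, Sig1)
                lp0 <- stats::plogis(-eta, log.p = TRUE) +
                    .dmvnormLog(Y, W0base %*% B, Sig0)
                probSum <- probSum + 1 / (1 + exp(lp0 - lp1))
            }
        }
    }
    post <- new("PosteriorDraws", draws = draws, settings = settings,
                priors = priors)
    new("CombinedLCMFit", posterior = post,
        classProb = probSum / (settings@nChains * nKeep),
        markers = colnames(Y), terms = terms, anchor = anchor,
        transform = list())
}

# rebuild (B, alpha, Sigma0, Sigma1) from one flattened draw
.unpackCombinedDraw <- function(fit, drawRow) {
    k <- length(fit@markers); qw <- length(fit@terms)
    d <- fit@posterior@draws[drawRow, ]
    B <- matrix(d[seq_len(k * qw)], qw, k,
                dimnames = list(fit@terms, fit@markers))
    alpha <- unname(d[startsWith(names(d), "alpha.")])
    ltri <- lower.tri(diag(k), diag = TRUE)
    unflat <- function(v) {
        S <- matrix(0, k, k); S[ltri] <- v
        S + t(S) - diag(diag(S), k)
    }
    list(B = B, alpha = alpha,
         sigma0 = unflat(unname(d[startsWith(names(d), "sigma0.")])),
         sigma1 = unflat(unname(d[startsWith(names(d), "sigma1.")])))
}

#' Classify subjects from a fitted latent class model
#'
#' @param fit a \linkS4class{CombinedLCMFit} or \linkS4class{SingleMarkerFit}
#' @param threshold posterior-probability threshold in (0, 1); a subject is
#'   assigned to the diseased class when P(D = 1 | data) >= threshold
#' @return list with \code{assignment} (0/1 vector), \code{probability},
#'   and \code{groupSizes} (named counts, summing to n)
#' @export
classifySubjects <- function(fit, threshold = 0.5) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly inside (0, 1)")
    pr <- classProbabilities(fit)
    a <- as.integer(pr >= threshold)
    list(assignment = a, probability = pr,
         groupSizes = c(diseased = sum(a), nonDiseased = sum(1L - a)))
}

#' Per-draw combined accuracy summaries for a multivariate fit
#'
#' For every retained draw: evaluate the class-conditional means at a
#' covariate profile x, form the optimal weights
#' a = (Sigma0 + Sigma1)^{-1} Delta(x), find the Youden cut-off on the
#' composite scale, and record cSensitivity, cSpecificity and cAUC; then
#' summarize across draws. \code{profile = "reference"} evaluates at x = 0
#' on the encoded scale (continuous covariates at the cohort mean,
#' categorical at the reference level); \code{profile = "average"} averages
#' the per-subject accuracies over the empirical covariate rows \code{X}
#' within each draw.
#'
#' @param fit a \linkS4class{CombinedLCMFit}
#' @param profile \code{"reference"}, \code{"average"}, or a numeric
#'   covariate vector on the encoded scale
#' @param X encoded covariate matrix (required for \code{"average"})
#' @param gridSize Youden grid resolution per draw
#' @return list with \code{cutoff} (median per-draw cut-off) and
#'   \code{table} (summary rows cSensitivity/cSpecificity/cAUC)
#' @export
combinedAccuracySummary <- function(fit, profile = "reference", X = NULL,
                                    gridSize = 501L) {
    m <- nrow(fit@posterior@draws)
    averaged <- identical(profile, "average")
    if (averaged && is.null(X))
        stop("profile = 'average' needs the encoded covariate matrix X")
    p <- sum(startsWith(colnames(fit@posterior@draws), "alpha.")) - 1L
    xs <- if (averaged) X
          else if (identical(profile, "reference"))
              matrix(0, 1, max(p, 0))
          else matrix(as.numeric(profile), 1)
    sens <- spec <- auc <- cut <- numeric(m)
    for (i in seq_len(m)) {
        pars <- .unpackCombinedDraw(fit, i)
        accS <- accP <- accA <- ct <- numeric(nrow(xs))
        for (r in seq_len(nrow(xs))) {
            x <- xs[r, ]
            muP <- meanStructure(pars$B, x, 1)
            muN <- meanStructure(pars$B, x, 0)
            w <- combinationWeights(muP, muN, pars$sigma0, pars$sigma1)
            acc <- combinedAccuracy(w, pars$sigma0, pars$sigma1,
                                    gridSize = gridSize)
            accS[r] <- acc$cSensitivity; accP[r] <- acc$cSpecificity
            accA[r] <- acc$cAUC; ct[r] <- acc$cutoff
        }
        sens[i] <- mean(accS); spec[i] <- mean(accP)
        auc[i] <- mean(accA); cut[i] <- mean(ct)
    }
    tab <- summarizeDraws(cbind(cSensitivity = sens, cSpecificity = spec,
                                cAUC = auc))
    list(cutoff = stats::median(cut), table = tab)
}
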