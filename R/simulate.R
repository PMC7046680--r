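#' Simulate a single-marker latent class cohort
#'
#' Generates data exactly under the single-marker model:
#' D_i ~ Bernoulli(prevalence), Y_i | D_i = 1 ~ N(muPos, sdPos^2),
#' Y_i | D_i = 0 ~ N(muNeg, sdNeg^2). The true labels are kept so recovery
#' can be scored.
#'
#' @param n cohort size (>= 1)
#' @param prevalence latent disease probability in [0, 1]
#' @param muPos,sdPos diseased-class mean and SD
#' @param muNeg,sdNeg non-diseased-class mean and SD
#' @param seed integer seed; identical inputs give identical cohorts
#' @param marker marker name (default "Y")
#' @return a \linkS4class{MarkerCohort} with true labels
#' @examples
#' simulateSingleMarkerCohort(50, 0.4, 1.5, 1, 0, 1, seed = 1)
#' @export
simulateSingleMarkerCohort <- function(n, prevalence, muPos, sdPos,
                                       muNeg, sdNeg, seed = 1L,
                                       marker = "Y") {
    if (n < 1) stop("n must be >= 1")
    stopifnot(prevalence >= 0, prevalence <= 1, sdPos > 0, sdNeg > 0)
    set.seed(seed)
    d <- stats::rbinom(n, 1L, prevalence)
    y <- stats::rnorm(n, ifelse(d == 1L, muPos, muNeg),
                      ifelse(d == 1L, sdPos, sdNeg))
    m <- matrix(y, ncol = 1, dimnames = list(NULL, marker))
    MarkerCohort(m, trueLabels = d)
}

#' Covariate generation specification
#'
#' A covariate spec is a named list; each element is either
#' \code{list(type = "normal", mean =, sd =)} for a continuous covariate or
#' \code{list(type = "categorical", levels =, probs =)} for a categorical
#' one. Categorical values are drawn by inverse-CDF on a single uniform for
#' cross-platform stability.
#'
#' @param spec named list as described
#' @param n number of subjects
#' @return data.frame of covariates (factors for categorical entries)
#' @keywords internal
.drawCovariates <- function(spec, n) {
    out <- list()
    for (nm in names(spec)) {
        s <- spec[[nm]]
        out[[nm]] <- switch(s$type,
            normal = stats::rnorm(n, s$mean, s$sd),
            categorical = {
                p <- s$probs / sum(s$probs)
                idx <- findInterval(stats::runif(n), cumsum(p)) + 1L
                factor(s$levels[idx], levels = s$levels)
            },
            stop("unknown covariate type: ", s$type))
    }
    as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate a covariate-adjusted multivariate latent class cohort
#'
#' Generative direction of the combined model: covariates x_i drawn from
#' \code{covariateSpec}; D_i ~ Bernoulli(plogis(alpha0 + alpha' x_i)) on
#' the encoded covariate scale; Y_i ~ MVN(mu(x_i, D_i), Sigma_{D_i}) with
#' per-marker means from \code{\link{meanStructure}}.
#'
#' @param beta coefficient matrix, 2(p+1) rows (intercept, covariate
#'   effects, disease effect, interaction effects) by k marker columns,
#'   with marker column names; p is the number of encoded covariate columns
#' @param alpha logistic coefficients (alpha0, alpha1..alphap)
#' @param sigma0,sigma1 k x k class-conditional covariances
#' @param covariateSpec named list of covariate distributions (see
#'   \code{.drawCovariates}); NULL for a covariate-free cohort
#' @param n cohort size
#' @param seed integer seed
#' @param standardize z-score continuous covariates before they enter the
#'   model (matches the fitting convention; default TRUE)
#' @return a \linkS4class{MarkerCohort} with true labels; the encoded
#'   design matrix used for generation is stored in
#'   \code{metadata()$encodedCovariates}
#' @export
simulateCombinedCohort <- function(beta, alpha, sigma0, sigma1,
                                   covariateSpec = NULL, n, seed = 1L,
                                   standardize = TRUE) {
    if (n < 1) stop("n must be >= 1")
    set.seed(seed)
    cov <- if (is.null(covariateSpec)) NULL
           else .drawCovariates(covariateSpec, n)
    X <- if (is.null(cov)) matrix(numeric(0), n, 0)
         else encodeCovariates(cov, standardize = standardize)
    p <- ncol(X)
    beta <- as.matrix(beta)
    k <- ncol(beta)
    if (nrow(beta) != 2 * (p + 1))
        stop("config error: beta needs 2(p+1) = ", 2 * (p + 1),
             " rows for ", p, " encoded covariate column(s)")
    if (length(alpha) != p + 1)
        stop("config error: alpha needs p+1 = ", p + 1, " entries")
    markers <- colnames(beta)
    if (is.null(markers)) markers <- paste0("M", seq_len(k))

    eta <- alpha[1] + if (p) drop(X %*% alpha[-1]) else 0
    d <- stats::rbinom(n, 1L, stats::plogis(eta))
    W <- cbind(1, X, d, X * d)
    mu <- W %*% beta
    Y <- matrix(NA_real_, n, k, dimnames = list(NULL, markers))
    i1 <- d == 1L
    if (any(i1))
        Y[i1, ] <- mu[i1, , drop = FALSE] +
            MASS::mvrnorm(sum(i1), numeric(k), as.matrix(sigma1))
    if (any(!i1))
        Y[!i1, ] <- mu[!i1, , drop = FALSE] +
            MASS::mvrnorm(sum(!i1), numeric(k), as.matrix(sigma0))
    out <- MarkerCohort(Y, covariates = cov, trueLabels = d)
    metadata(out)$encodedCovariates <- X
    out
}

#' Published-cohort-style GVHD transplant scenario
#'
#' A ready-made combined-model scenario emulating the moments of the
#' allogeneic-HSCT cohort the package's methods were designed around:
#' 94 subjects; marginal latent GVHD prevalence 0.457; class-conditional
#' marker means (SD) of log10-LDH 2.68 (0.11) diseased vs 2.62 (0.14)
#' non-diseased, UA 3.91 (0.87) vs 3.76 (0.87) mg/dL, Cr 0.95 (0.16) vs
#' 0.88 (0.13) mg/dL; within-class marker correlation 0.3; covariates age ~
#' N(35, 10), donor/patient gender (4 levels), GVHD prophylaxis (2 levels)
#' and conditioning regimen (3 levels). Covariates are generated but carry
#' no marker or prevalence effects by default (only the within-group
#' moments are known); \code{alphaCov} and \code{betaCov} switch effects
#' on. \code{separation} multiplies the diseased/non-diseased mean gap of
#' every marker, for stress-testing combination accuracy.
#'
#' @param n cohort size (default 94)
#' @param separation multiplier on all class mean differences (default 1)
#' @param alphaCov optional vector of logistic covariate effects (length =
#'   number of encoded covariate columns, here 7)
#' @param betaCov optional p x k matrix of covariate effects on the marker
#'   means (both classes)
#' @return list with \code{beta}, \code{alpha}, \code{sigma0},
#'   \code{sigma1}, \code{covariateSpec}, \code{n}, \code{markers} — the
#'   arguments of \code{\link{simulateCombinedCohort}}
#' @examples
#' sc <- gvhdScenario()
#' x <- simulateScenario(sc, seed = 42)
#' table(trueLabels(x))
#' @export
gvhdScenario <- function(n = 94L, separation = 1, alphaCov = NULL,
                         betaCov = NULL) {
    markers <- c("LDH", "UA", "Cr")
    muPos <- c(LDH = 2.68, UA = 3.91, Cr = 0.95)
    muNeg <- c(LDH = 2.62, UA = 3.76, Cr = 0.88)
    sdPos <- c(LDH = 0.11, UA = 0.87, Cr = 0.16)
    sdNeg <- c(LDH = 0.14, UA = 0.87, Cr = 0.13)
    gap <- (muPos - muNeg) * separation
    rho <- 0.3
    corr <- matrix(rho, 3, 3); diag(corr) <- 1
    sigma1 <- diag(sdPos) %*% corr %*% diag(sdPos)
    sigma0 <- diag(sdNeg) %*% corr %*% diag(sdNeg)
    dimnames(sigma0) <- dimnames(sigma1) <- list(markers, markers)
    covariateSpec <- list(
        age = list(type = "normal", mean = 35, sd = 10),
        dpGender = list(type = "categorical",
                        levels = c("M-M", "M-F", "F-F", "F-M"),
                        probs = c(0.20, 0.34, 0.16, 0.30)),
        prophylaxis = list(type = "categorical",
                           levels = c("CSA+MTX", "CSA+MTX+ATG"),
                           probs = c(0.86, 0.14)),
        conditioning = list(type = "categorical",
                            levels = c("Bu-Cy", "Bu-Fu", "Bu-Fu-ATG"),
                            probs = c(0.56, 0.31, 0.13)))
    p <- 1L + 3L + 1L + 2L          # encoded columns (dummies, z-scored age)
    bCov <- if (is.null(betaCov)) matrix(0, p, 3) else as.matrix(betaCov)
    beta <- rbind(muNeg,            # beta0: non-diseased intercepts
                  bCov,             # covariate effects on both classes
                  gap,              # betaD: disease shift
                  matrix(0, p, 3))  # no covariate-by-disease interactions
    colnames(beta) <- markers
    alpha <- c(.logit(0.457), if (is.null(alphaCov)) rep(0, p) else alphaCov)
    list(beta = beta, alpha = alpha, sigma0 = sigma0, sigma1 = sigma1,
         covariateSpec = covariateSpec, n = as.integer(n),
         markers = markers)
}

#' Simulate a cohort from a scenario
#'
#' @param scenario a scenario list as returned by \code{\link{gvhdScenario}}
#' @param seed integer seed
#' @return a \linkS4class{MarkerCohort} with true labels
#' @export
simulateScenario <- function(scenario, seed = 1L)
    simulateCombinedCohort(scenario$beta, scenario$alpha, scenario$sigma0,
                           scenario$sigma1, scenario$covariateSpec,
                           scenario$n, seed = seed)
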