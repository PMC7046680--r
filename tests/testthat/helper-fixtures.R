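# shared fixtures, built in code

# small cohort with two markers and mixed covariates
makeTinyCohort <- function(n = 12, seed = 42) {
    set.seed(seed)
    y <- cbind(LDH = rnorm(n, 2.6, 0.12), Cr = rnorm(n, 0.9, 0.15))
    cov <- data.frame(age = round(rnorm(n, 35, 10), 1),
                      sex = factor(sample(c("F", "M"), n, replace = TRUE),
                                   levels = c("F", "M")))
    MarkerCohort(y, covariates = cov)
}

# random SPD matrix of dimension k
randomSPD <- function(k, scale = 1) {
    A <- matrix(rnorm(k * k), k)
    crossprod(A) / k * scale + diag(0.1, k)
}

# Monte-Carlo AUC of the composite a'Y from paired class draws
mcCombinedAUC <- function(a, muPos, muNeg, sigma1, sigma0, nDraw) {
    yp <- MASS::mvrnorm(nDraw, muPos, sigma1) %*% a
    yn <- MASS::mvrnorm(nDraw, muNeg, sigma0) %*% a
    mean(yp > yn)
}
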