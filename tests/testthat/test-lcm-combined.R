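test_that("mean structure evaluates the regression form exactly", {
    expect_equal(meanStructure(c(0, 0, 0, 0), x = 1, d = 1), 0)
    expect_equal(meanStructure(c(1, 2, 3, -1), x = 0.5, d = 1), 4.5)
    # d = 0 ignores the disease and interaction coefficients
    expect_equal(meanStructure(c(1, 2, 99, 99), x = 0.5, d = 0), 2)
    B <- cbind(m1 = c(1, 0, 1, 0), m2 = c(0, 1, 0, 1))
    expect_equal(meanStructure(B, x = 2, d = 1), c(m1 = 2, m2 = 4))
    expect_error(meanStructure(c(1, 2, 3), x = 1, d = 1), "dimension")
})

test_that("disease probability is the inverse-logit and is monotone", {
    expect_equal(diseaseProbability(0, numeric(0)), 0.5)
    expect_equal(diseaseProbability(qlogis(0.457), numeric(0)), 0.457)
    grid <- seq(-3, 3, length.out = 25)
    p <- vapply(grid, function(a1) diseaseProbability(c(0.2, a1, -1), c(1, 0.5)),
                numeric(1))
    expect_true(all(diff(p) > 0))
    expect_error(diseaseProbability(c(0, 1), c(1, 2)), "dimension")
})

test_that("combined fit recovers known parameters on identifiable data", {
    beta <- rbind(c(0.5, 1.0, 0.2), c(0.4, -0.3, 0.2), c(2.0, 1.6, 2.4),
                  c(0, 0, 0))
    colnames(beta) <- c("LDH", "UA", "Cr")
    S0 <- diag(3) * 0.8; S1 <- matrix(0.3, 3, 3); diag(S1) <- 1
    cs <- list(g = list(type = "categorical", levels = c("a", "b"),
                        probs = c(0.5, 0.5)))
    x <- simulateCombinedCohort(beta, c(-0.3, 0.6), S0, S1, cs, n = 400,
                                seed = 21)
    Y <- markerMatrix(x)
    X <- S4Vectors::metadata(x)$encodedCovariates
    fit <- fitCombinedLCM(Y, X, settings = mcmcSettings(8000, 3000, 7, seed = 22))
    s <- summarizeDraws(posteriorDraws(fit))
    truth <- c(beta.LDH.D = 2.0, beta.UA.D = 1.6, beta.Cr.D = 2.4)
    for (nm in names(truth)) {
        i <- match(nm, s$parameter)
        expect_lt(abs(s$mean[i] - truth[[nm]]), 3 * s$sd[i])
    }
    # classification approaches the Bayes rate on well-separated data
    expect_gt(mean((classProbabilities(fit) >= 0.5) == trueLabels(x)), 0.85)
    # anchor: the Cr disease effect is positive in every retained draw
    expect_true(all(posteriorDraws(fit)[, "beta.Cr.D"] > 0))
    # every covariance draw is symmetric positive definite
    for (i in seq(1, nrow(posteriorDraws(fit)), by = 25)) {
        pars <- lcmROC:::.unpackCombinedDraw(fit, i)
        expect_no_error(chol(pars$sigma0))
        expect_no_error(chol(pars$sigma1))
    }
})

test_that("combined fit validates its inputs", {
    Y <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
    X <- matrix(rnorm(29), 29, 1)
    expect_error(fitCombinedLCM(Y, X), "dimension")
    expect_error(fitCombinedLCM(Y[, 1, drop = FALSE]), "k >= 2")
    Y2 <- Y; Y2[3, 1] <- NA
    expect_error(fitCombinedLCM(Y2), "finite")
})

test_that("subject classification partitions the cohort at the threshold", {
    beta <- rbind(c(0, 0), c(3, 4))
    colnames(beta) <- c("m1", "Cr")
    x <- simulateCombinedCohort(beta, 0.1, diag(2), diag(2), NULL, n = 150,
                                seed = 23)
    fit <- fitCombinedLCM(markerMatrix(x),
                          settings = mcmcSettings(1500, 500, 2, seed = 24))
    cls <- classifySubjects(fit)
    expect_equal(sum(cls$groupSizes), 150L)
    expect_equal(cls$assignment, as.integer(cls$probability >= 0.5))
    expect_gt(mean(cls$assignment == trueLabels(x)), 0.95)
    strict <- classifySubjects(fit, threshold = 0.999999)
    expect_lte(sum(strict$assignment), sum(cls$assignment))
    expect_error(classifySubjects(fit, threshold = 1.2), "threshold")
})

test_that("per-draw combined accuracy summary is coherent", {
    beta <- rbind(c(0, 0), c(1.5, 2))
    colnames(beta) <- c("m1", "Cr")
    x <- simulateCombinedCohort(beta, 0, diag(2), diag(2), NULL, n = 300,
                                seed = 25)
    fit <- fitCombinedLCM(markerMatrix(x),
                          settings = mcmcSettings(2000, 800, 6, seed = 26))
    acc <- combinedAccuracySummary(fit)
    tab <- acc$table
    expect_setequal(tab$parameter, c("cSensitivity", "cSpecificity", "cAUC"))
    expect_true(all(tab$criLow <= tab$median & tab$median <= tab$criHigh))
    expect_true(all(tab$mean >= 0 & tab$mean <= 1))
    # truth: a = (2 Sigma)^-1 delta = delta/2, cAUC = pnorm(sqrt(a'delta))
    cAUCtrue <- pnorm(sqrt(sum(c(1.5, 2)^2) / 2))
    i <- match("cAUC", tab$parameter)
    expect_lt(abs(tab$mean[i] - cAUCtrue), 0.1)
})

test_that("row permutation leaves the likelihood-relevant quantities unchanged", {
    # the deterministic parts: mvn log-density sums are permutation-invariant
    set.seed(27)
    Y <- matrix(rnorm(90), 30, 3)
    mu <- matrix(rnorm(90), 30, 3)
    S <- randomSPD(3)
    ll <- lcmROC:::.dmvnormLog(Y, mu, S)
    p <- sample(30)
    llPerm <- lcmROC:::.dmvnormLog(Y[p, ], mu[p, ], S)
    expect_equal(sum(ll), sum(llPerm))
    expect_equal(ll[p], llPerm)
})
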