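test_that("retained draw counts follow the settings", {
    s <- mcmcSettings(20000, 8000, 25, seed = 1)
    expect_equal(retainedDrawCount(s), 480L)
    expect_equal(retainedDrawCount(combinedMCMCSettings(seed = 1)), 400L)
    x <- simulateSingleMarkerCohort(60, 0.5, 2.5, 1, 0, 1, seed = 2)
    short <- suppressWarnings(mcmcSettings(600, 100, 7, seed = 3))
    fit <- fitSingleMarkerLCM(markerMatrix(x)[, 1], settings = short)
    expect_equal(nrow(posteriorDraws(fit)), (600L - 100L) %/% 7L)
    expect_warning(mcmcSettings(200, 100, 25), "fewer than 100")
    expect_error(mcmcSettings(100, 100, 1), "burnIn")
})

test_that("single-marker fit recovers well-separated truth and is reproducible", {
    x <- simulateSingleMarkerCohort(500, 0.5, 3, 1, 0, 1, seed = 4)
    y <- markerMatrix(x)[, 1]
    fit <- fitSingleMarkerLCM(y, settings = mcmcSettings(4000, 1000, 5, seed = 5))
    pm <- colMeans(posteriorDraws(fit))
    s <- summarizeDraws(posteriorDraws(fit))
    sdm <- s$sd[match(c("muPos", "muNeg"), s$parameter)]
    expect_lt(abs(pm["muPos"] - 3), 3 * sdm[1])
    expect_lt(abs(pm["muNeg"] - 0), 3 * sdm[2])
    expect_lt(abs(pm["pi"] - 0.5), 0.1)
    # anchor constraint holds in every retained draw
    d <- posteriorDraws(fit)
    expect_true(all(d[, "muPos"] > d[, "muNeg"]))
    # seed contract
    fit2 <- fitSingleMarkerLCM(y, settings = mcmcSettings(4000, 1000, 5, seed = 5))
    expect_identical(posteriorDraws(fit), posteriorDraws(fit2))
    expect_error(fitSingleMarkerLCM(rep(1, 100)), "zero variance")
})

test_that("posterior class probabilities follow per-draw Bayes allocation", {
    x <- simulateSingleMarkerCohort(1000, 0.5, 2.5, 1, 0, 1, seed = 6)
    y <- markerMatrix(x)[, 1]
    fit <- fitSingleMarkerLCM(y, settings = mcmcSettings(3000, 1000, 4, seed = 7))
    pr <- classProbabilities(fit)
    expect_true(all(pr >= 0 & pr <= 1))
    # law of total expectation: mean class probability ~ posterior mean of pi
    expect_lt(abs(mean(pr) - mean(posteriorDraws(fit)[, "pi"])), 0.02)
    # moderately extreme values resolve towards the right class (the far
    # tails are dominated by whichever class draw has the larger variance,
    # so the clean limit only holds with equal variances — tested below)
    pTail <- posteriorClassProbabilities(fit, c(-4, 7))
    expect_lt(pTail[1], 0.1)
    expect_gt(pTail[2], 0.9)
    # scoring the fitted data reproduces the stored probabilities
    expect_equal(posteriorClassProbabilities(fit, y), pr, tolerance = 1e-12)
})

test_that("fixed-variance equal-density point scores probability ~ pi", {
    # symmetric two-component instance: at the midpoint the allocation is 0.5
    set.seed(8)
    y <- c(rnorm(100, -2), rnorm(100, 2))
    fit <- fitSingleMarkerLCM(y, settings = mcmcSettings(2000, 500, 3, seed = 9),
                              fixedVariances = c(1, 1))
    pMid <- posteriorClassProbabilities(fit, 0)
    expect_lt(abs(pMid - 0.5), 0.05)
    # with equal fixed variances the tail limits are exact
    pTail <- posteriorClassProbabilities(fit, c(-20, 20))
    expect_lt(pTail[1], 1e-6)
    expect_gt(pTail[2], 1 - 1e-6)
})

test_that("per-draw accuracy summary has coherent credible intervals", {
    x <- simulateSingleMarkerCohort(300, 0.45, 2, 1, 0, 1, seed = 10)
    fit <- fitSingleMarkerLCM(markerMatrix(x)[, 1],
                              settings = mcmcSettings(3000, 1000, 10, seed = 11))
    acc <- singleAccuracySummary(fit)
    tab <- acc$table
    expect_setequal(tab$parameter, c("sensitivity", "specificity", "AUC"))
    expect_true(all(tab$criLow <= tab$median & tab$median <= tab$criHigh))
    expect_true(all(tab$mean >= 0 & tab$mean <= 1))
    # the Youden cut-off sits between the class means on average
    pm <- colMeans(posteriorDraws(fit))
    expect_gt(acc$cutoff, pm["muNeg"])
    expect_lt(acc$cutoff, pm["muPos"])
})
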