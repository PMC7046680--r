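test_that("single-marker generator honours prevalence and the seed contract", {
    x <- simulateSingleMarkerCohort(50, 1, 2, 1, 0, 1, seed = 1)
    expect_true(all(trueLabels(x) == 1L))
    x <- simulateSingleMarkerCohort(10000, 0.4, 2, 1, 0, 1, seed = 2)
    expect_lt(abs(mean(trueLabels(x)) - 0.4), 0.015)  # 3-sigma binomial bound
    a <- simulateSingleMarkerCohort(100, 0.3, 1, 1, 0, 1, seed = 7)
    b <- simulateSingleMarkerCohort(100, 0.3, 1, 1, 0, 1, seed = 7)
    expect_identical(markerMatrix(a), markerMatrix(b))
    expect_identical(trueLabels(a), trueLabels(b))
    expect_error(simulateSingleMarkerCohort(0, 0.5, 1, 1, 0, 1), "n")
})

test_that("combined generator follows the logistic label mechanism and covariances", {
    beta <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 0))
    colnames(beta) <- c("M1", "M2")
    cs <- list(z = list(type = "normal", mean = 0, sd = 1))
    # alpha all zero: label fraction ~ 0.5
    x <- simulateCombinedCohort(beta, c(0, 0), diag(2), diag(2), cs,
                                n = 10000, seed = 3)
    expect_lt(abs(mean(trueLabels(x)) - 0.5), 0.015)
    # identity covariances: within-class correlations vanish
    d <- trueLabels(x); m <- markerMatrix(x)
    expect_lt(abs(cor(m[d == 0, 1], m[d == 0, 2])), 0.05)
    expect_lt(abs(cor(m[d == 1, 1], m[d == 1, 2])), 0.05)
    # logistic mechanism within covariate strata
    cs2 <- list(g = list(type = "categorical", levels = c("a", "b"),
                         probs = c(0.5, 0.5)))
    x2 <- simulateCombinedCohort(beta, c(-0.5, 1), diag(2), diag(2), cs2,
                                 n = 20000, seed = 4, standardize = FALSE)
    g <- as.data.frame(covariateTable(x2))$g
    d2 <- trueLabels(x2)
    expect_lt(abs(mean(d2[g == "a"]) - plogis(-0.5)), 0.02)
    expect_lt(abs(mean(d2[g == "b"]) - plogis(0.5)), 0.02)
    # seed contract
    y1 <- simulateCombinedCohort(beta, c(0, 0), diag(2), diag(2), cs, 50, seed = 5)
    y2 <- simulateCombinedCohort(beta, c(0, 0), diag(2), diag(2), cs, 50, seed = 5)
    expect_identical(markerMatrix(y1), markerMatrix(y2))
    expect_error(simulateCombinedCohort(beta[1:3, ], c(0, 0), diag(2),
                                        diag(2), cs, 10), "config error")
    expect_error(simulateCombinedCohort(beta, c(0, 0, 0), diag(2), diag(2),
                                        cs, 10), "config error")
})

test_that("the transplant-cohort preset encodes the published moments", {
    sc <- gvhdScenario()
    expect_equal(sc$n, 94L)
    expect_equal(plogis(sc$alpha[1]), 0.457, tolerance = 1e-12)
    # class-conditional intercepts are the group means; betaD their gap
    expect_equal(unname(sc$beta[1, ]), c(2.62, 3.76, 0.88))
    p <- (nrow(sc$beta) - 2) / 2           # encoded covariate columns
    expect_equal(unname(sc$beta[p + 2, ]), c(2.68 - 2.62, 3.91 - 3.76,
                                             0.95 - 0.88))
    expect_equal(sqrt(diag(sc$sigma1)), c(LDH = 0.11, UA = 0.87, Cr = 0.16))
    expect_equal(sqrt(diag(sc$sigma0)), c(LDH = 0.14, UA = 0.87, Cr = 0.13))
})

test_that("preset moments are recovered by large-sample simulation", {
    sc <- gvhdScenario(n = 50000)
    x <- simulateScenario(sc, seed = 6)
    d <- trueLabels(x); m <- markerMatrix(x)
    expect_lt(abs(mean(d) - 0.457), 3 * sqrt(0.457 * 0.543 / 50000))
    expect_lt(abs(mean(m[d == 1, "LDH"]) - 2.68), 0.01)
    expect_lt(abs(mean(m[d == 0, "LDH"]) - 2.62), 0.01)
    expect_lt(abs(sd(m[d == 1, "Cr"]) - 0.16), 0.01)
    expect_lt(abs(cor(m[d == 1, "LDH"], m[d == 1, "UA"]) - 0.3), 0.03)
})
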