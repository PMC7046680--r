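test_that("binormal sensitivity/specificity obey their closed forms", {
    expect_equal(binormalSensitivity(1, muPos = 1, varPos = 2), 0.5)
    expect_equal(binormalSpecificity(0, muNeg = 0, varNeg = 5), 0.5)
    expect_equal(binormalSensitivity(-1e6, 0, 1), 1)
    expect_equal(binormalSpecificity(1e6, 0, 1), 1)
    # Monte-Carlo oracle
    set.seed(1)
    expect_equal(binormalSensitivity(0, 1, 1), mean(rnorm(1e6, 1, 1) > 0),
                 tolerance = 0.002)
    expect_equal(binormalSpecificity(1, 0, 4), mean(rnorm(1e6, 0, 2) <= 1),
                 tolerance = 0.002)
    expect_error(binormalSensitivity(0, 0, -1), "varPos")
})

test_that("binormal AUC matches pairwise Monte-Carlo and is shift-invariant", {
    expect_equal(binormalAUC(3, 1, 3, 2), 0.5)
    set.seed(2)
    expect_equal(binormalAUC(2, 1, 0, 1),
                 mean(rnorm(1e6, 2, 1) > rnorm(1e6, 0, 1)),
                 tolerance = 0.002)
    expect_equal(binormalAUC(2, 1.3, 0, 0.7),
                 binormalAUC(7, 1.3, 5, 0.7))
})

test_that("Youden cut-off matches symmetry and the equal-density crossing", {
    yd <- youdenCutoff(1, 1, -1, 1)
    expect_equal(yd$cutoff, 0, tolerance = 1e-8)  # grid midpoint is exact
    expect_equal(yd$J, 2 * pnorm(1) - 1, tolerance = 1e-4)
    # unequal variances: compare with the analytic equal-density crossing
    # between the component means (root of f+ = f-)
    set.seed(3)
    for (i in 1:20) {
        muN <- rnorm(1); muP <- muN + runif(1, 0.5, 3)
        vP <- runif(1, 0.3, 2); vN <- runif(1, 0.3, 2)
        root <- uniroot(function(c)
            dnorm(c, muP, sqrt(vP)) - dnorm(c, muN, sqrt(vN)),
            lower = muN, upper = muP, tol = 1e-12)$root
        yd <- youdenCutoff(muP, vP, muN, vN, gridSize = 2001L)
        grid <- seq(min(muP, muN) - 4 * sqrt(max(vP, vN)),
                    max(muP, muN) + 4 * sqrt(max(vP, vN)),
                    length.out = 2001L)
        expect_lt(abs(yd$cutoff - root), diff(grid[1:2]) + 1e-12)
    }
})

test_that("ROC curve is monotone, anchored at the corners, and integrates to the AUC", {
    rc <- rocCurve(1.2, 1.4, 0, 0.8, gridSize = 10001L)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
    expect_lt(rc$fpr[1] + rc$tpr[1], 1e-3)
    expect_gt(rc$fpr[nrow(rc)] + rc$tpr[nrow(rc)], 2 - 1e-3)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(trap, binormalAUC(1.2, 1.4, 0, 0.8), tolerance = 1e-3)
    # no separation: the diagonal
    rc0 <- rocCurve(0.5, 1, 0.5, 1)
    expect_lt(max(abs(rc0$tpr - rc0$fpr)), 1e-9)
})

test_that("separation Delta matches the equal-variance closed form and its limits", {
    expect_equal(separationDelta(0, 1, 0, 1), 0, tolerance = 1e-6)
    expect_equal(separationDelta(2, 1, 0, 1), 1 - 2 * pnorm(-1),
                 tolerance = 1e-6)
    expect_gt(separationDelta(50, 1, 0, 1), 1 - 1e-9)
    # better-separated marker scores higher
    expect_gt(separationDelta(1.5, 1, 0, 1), separationDelta(0.5, 1, 0, 1))
})

test_that("combination weights solve the linear system", {
    w <- combinationWeights(c(1, 0, 0), c(0, 0, 0), diag(3) * 0.5,
                            diag(3) * 0.5)
    expect_equal(w$a, c(1, 0, 0))
    # hand-worked 2x2: (Sigma0+Sigma1) = [[2,1],[1,2]], Delta = (1,1)
    w2 <- combinationWeights(c(1, 1), c(0, 0),
                             matrix(c(1, .5, .5, 1), 2),
                             matrix(c(1, .5, .5, 1), 2))
    expect_equal(w2$a, c(1 / 3, 1 / 3))
    set.seed(4)
    for (i in 1:10) {
        S0 <- randomSPD(3); S1 <- randomSPD(3)
        delta <- rnorm(3)
        w <- combinationWeights(delta, rep(0, 3), S0, S1)
        expect_lt(max(abs((S0 + S1) %*% w$a - delta)), 1e-10)
    }
})

test_that("combined accuracy matches its Monte-Carlo oracle and degenerate cases", {
    w <- combinationWeights(c(1, 0, 0), c(0, 0, 0), diag(3), diag(3))
    acc <- combinedAccuracy(w, diag(3), diag(3))
    expect_equal(acc$cAUC, pnorm(sqrt(0.5)))
    set.seed(5)
    mc <- mcCombinedAUC(w$a, c(1, 0, 0), c(0, 0, 0), diag(3), diag(3), 2e5)
    expect_equal(acc$cAUC, mc, tolerance = 0.004)
    # zero separation
    w0 <- combinationWeights(rep(0, 2), rep(0, 2), diag(2), diag(2))
    expect_equal(combinedAccuracy(w0, diag(2), diag(2))$cAUC, 0.5)
    # invariance under per-marker rescaling (diagonal similarity)
    set.seed(6)
    S0 <- randomSPD(3); S1 <- randomSPD(3); delta <- c(0.8, -0.2, 0.5)
    D <- diag(c(2, 0.5, 10))
    a1 <- combinedAccuracy(combinationWeights(delta, rep(0, 3), S0, S1),
                           S0, S1)$cAUC
    a2 <- combinedAccuracy(
        combinationWeights(drop(D %*% delta), rep(0, 3),
                           D %*% S0 %*% D, D %*% S1 %*% D),
        D %*% S0 %*% D, D %*% S1 %*% D)$cAUC
    expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("sensitivity decreases and specificity increases in the cut-off", {
    grid <- seq(-5, 5, length.out = 200)
    expect_true(all(diff(binormalSensitivity(grid, 0.7, 1.3)) <= 0))
    expect_true(all(diff(binormalSpecificity(grid, -0.2, 0.6)) >= 0))
})
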