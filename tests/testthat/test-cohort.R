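test_that("cohort construction, accessors and validity", {
    x <- makeTinyCohort()
    expect_s4_class(x, "MarkerCohort")
    expect_equal(dim(markerMatrix(x)), c(12L, 2L))
    expect_equal(colnames(markerMatrix(x)), c("LDH", "Cr"))
    expect_equal(nrow(covariateTable(x)), 12L)
    expect_null(trueLabels(x))
    expect_error(MarkerCohort(matrix(1:4, 2), covariates = data.frame(a = 1:3)),
                 "equal row counts")
    expect_error(MarkerCohort(matrix(1, 1, 1), trueLabels = 2), "0/1")
})

test_that("cohort save/load round-trips exactly", {
    x <- simulateSingleMarkerCohort(5, 0.5, 1, 1, 0, 1, seed = 9)
    cov <- data.frame(age = c(21.5, 34.2, 45.1, 29.9, 60.3),
                      grp = factor(c("a", "b", "a", "b", "a")))
    x <- MarkerCohort(markerMatrix(x), covariates = cov,
                      trueLabels = trueLabels(x))
    f <- tempfile(fileext = ".csv")
    writeCohort(x, f)
    y <- readCohort(f, markerCols = "Y", covariateCols = c("age", "grp"),
                    idCol = "subject_id", labelCol = "true_label",
                    categoricalCols = "grp")
    expect_equal(markerMatrix(y), markerMatrix(x))
    expect_equal(as.data.frame(covariateTable(y)),
                 as.data.frame(covariateTable(x)),
                 ignore_attr = TRUE)
    expect_equal(trueLabels(y), trueLabels(x))
    expect_equal(subjectIds(y), subjectIds(x))
})

test_that("a YAML schema file drives cohort loading", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("id,LDH,Cr,sex", "s1,2.5,0.9,F", "s2,2.7,1.1,M"), f)
    sf <- tempfile(fileext = ".yaml")
    writeLines(c("markerCols: [LDH, Cr]", "covariateCols: [sex]",
                 "categoricalCols: [sex]", "idCol: id"), sf)
    x <- readCohortWithSchema(f, sf)
    expect_equal(subjectIds(x), c("s1", "s2"))
    expect_true(is.factor(covariateTable(x)$sex))
    writeLines(c("markerCols: [LDH]", "bogusField: 1"), sf)
    expect_error(readCohortWithSchema(f, sf), "bogusField")
})

test_that("readCohort reports schema and parse errors precisely", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("id,LDH,UA", "s1,100,3.5", "s2,oops,4.1"), f)
    expect_error(readCohort(f, markerCols = c("LDH", "Cr"), idCol = "id"),
                 "Cr")
    expect_error(readCohort(f, markerCols = c("LDH", "UA"), idCol = "id"),
                 "row 2")
})

test_that("preprocessing transforms, excludes outliers and logs exclusions", {
    y <- cbind(LDH = c(100, 110, 120, 130, 105, 115, 1e5),
               Cr = c(0.9, 1.0, 1.1, 0.95, 1.05, 0.85, 1.0))
    x <- MarkerCohort(y)
    out <- preprocessCohort(x, transforms = c(LDH = "log10"))
    m <- markerMatrix(out)
    expect_equal(unname(m[1, "LDH"]), 2)           # log10(100)
    expect_equal(nrow(m), 6L)                      # extreme row dropped
    excl <- S4Vectors::metadata(out)$exclusions
    expect_equal(nrow(excl), 1L)
    expect_equal(excl$subject_id, "S7")
    expect_match(excl$reason, "outlier in LDH")
    # exclusion count + retained count partitions the input
    expect_equal(nrow(excl) + nrow(m), nrow(y))
    # log10 of a non-positive value is an error naming the row
    bad <- MarkerCohort(cbind(LDH = c(100, 0, 120)))
    expect_error(preprocessCohort(bad, transforms = c(LDH = "log10")),
                 "row 2")
})

test_that("preprocessing is idempotent once applied", {
    x <- makeTinyCohort(n = 40)
    once <- preprocessCohort(x, outlierRule = "robust-z")
    twice <- preprocessCohort(once, outlierRule = "robust-z")
    expect_equal(markerMatrix(twice), markerMatrix(once))
    expect_equal(nrow(S4Vectors::metadata(twice)$exclusions), 0L)
})

test_that("covariate encoding: dummies, z-scores and recorded transform", {
    cov <- data.frame(age = c(20, 30, 40),
                      grp = factor(c("a", "b", "c"), levels = c("a", "b", "c")))
    X <- encodeCovariates(cov)
    expect_equal(colnames(X), c("age", "grp.b", "grp.c"))
    expect_equal(mean(X[, "age"]), 0)
    expect_equal(sd(X[, "age"]), 1)
    expect_equal(unname(X[, "grp.b"]), c(0, 1, 0))
    tr <- attr(X, "transform")
    expect_equal(tr$age$center, 30)
    expect_equal(tr$grp$levels, c("a", "b", "c"))
})
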