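#' Screen covariates for association with markers or provisional disease
#'
#' Mirrors the pre-modelling screening step: a covariate is retained when it
#' is associated, at significance level \code{alpha} (default 20\%, chosen
#' deliberately looser than 5\% so weak but relevant covariates survive to
#' the latent class stage), with (a) any marker, by the overall F-test of a
#' linear regression of that marker on the covariate, or (b) the
#' provisional disease labels, by the likelihood-ratio test of a binary
#' logistic regression. Constant covariates are skipped with a warning.
#'
#' @param cohort a \linkS4class{MarkerCohort}
#' @param labels provisional 0/1 disease labels (e.g. majority vote of
#'   single-marker classifications); NULL skips the logistic arm
#' @param alpha significance level in (0, 1]
#' @return character vector of selected covariate names; the per-test
#'   p-values are attached as attribute \code{"pvalues"}
#' @export
screenCovariates <- function(cohort, labels = NULL, alpha = 0.20) {
    if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
    cov <- as.data.frame(covariateTable(cohort))
    m <- markerMatrix(cohort)
    if (!is.null(labels)) stopifnot(length(labels) == nrow(m))
    selected <- character(); pvals <- list()
    for (nm in colnames(cov)) {
        v <- cov[[nm]]
        if (length(unique(v[!is.na(v)])) < 2L) {
            warning("covariate '", nm, "' is constant; skipped")
            next
        }
        ps <- numeric()
        for (mk in colnames(m)) {
            f <- stats::lm(m[, mk] ~ v)
            a <- stats::anova(f)
            ps[paste0("lm.", mk)] <- a$`Pr(>F)`[1]
        }
        if (!is.null(labels)) {
            g <- stats::glm(labels ~ v, family = stats::binomial())
            g0 <- stats::glm(labels ~ 1, family = stats::binomial())
            ps["logistic"] <- stats::pchisq(g0$deviance - g$deviance,
                                            df = g0$df.residual -
                                                g$df.residual,
                                            lower.tail = FALSE)
        }
        pvals[[nm]] <- ps
        if (any(ps < alpha)) selected <- c(selected, nm)
    }
    attr(selected, "pvalues") <- pvals
    selected
}

#' Compare two latent groups on markers and covariates
#'
#' Builds a demographics-style comparison of the assigned diseased vs
#' non-diseased groups: per continuous variable (markers and continuous
#' covariates) the group means (SD) and a two-sided Welch t-test p-value;
#' per categorical covariate the level counts (\%) and a chi-square test
#' p-value (reported as NA, with a warning, when an expected cell count is
#' zero).
#'
#' @param cohort a \linkS4class{MarkerCohort}
#' @param assignment 0/1 vector partitioning the cohort
#' @return data.frame with columns variable, level, group1 (diseased
#'   summary), group0, test, p
#' @export
compareGroups <- function(cohort, assignment) {
    assignment <- as.integer(assignment)
    stopifnot(length(assignment) == ncol(cohort),
              all(assignment %in% c(0L, 1L)))
    if (!sum(assignment) || !sum(1L - assignment))
        stop("both groups must be non-empty")
    g1 <- assignment == 1L
    rows <- list()
    contRow <- function(name, v) {
        tt <- if (sum(g1) < 2 || sum(!g1) < 2)
            list(p.value = NA_real_)       # a 1-subject group: no t-test
        else if (stats::sd(v[g1]) == 0 && stats::sd(v[!g1]) == 0 &&
                 mean(v[g1]) == mean(v[!g1]))
            list(statistic = 0, p.value = 1)
        else stats::t.test(v[g1], v[!g1])
        data.frame(variable = name, level = NA_character_,
                   group1 = sprintf("%.2f (%.2f)", mean(v[g1]),
                                    stats::sd(v[g1])),
                   group0 = sprintf("%.2f (%.2f)", mean(v[!g1]),
                                    stats::sd(v[!g1])),
                   test = "t", p = tt$p.value)
    }
    m <- markerMatrix(cohort)
    for (mk in colnames(m)) rows[[length(rows) + 1L]] <- contRow(mk, m[, mk])
    cov <- as.data.frame(covariateTable(cohort))
    for (nm in colnames(cov)) {
        v <- cov[[nm]]
        if (is.numeric(v)) {
            rows[[length(rows) + 1L]] <- contRow(nm, v)
        } else {
            tab <- table(factor(v), factor(as.integer(g1), levels = c(1, 0)))
            exp0 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
            p <- if (any(exp0 == 0)) {
                warning("zero expected cell count for '", nm,
                        "'; chi-square p undefined")
                NA_real_
            } else suppressWarnings(stats::chisq.test(tab)$p.value)
            for (lv in rownames(tab)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    variable = nm, level = lv,
                    group1 = sprintf("%d (%.1f%%)", tab[lv, "1"],
                                     100 * tab[lv, "1"] / sum(g1)),
                    group0 = sprintf("%d (%.1f%%)", tab[lv, "0"],
                                     100 * tab[lv, "0"] / sum(!g1)),
                    test = "chisq",
                    p = if (lv == rownames(tab)[1]) p else NA_real_)
            }
        }
    }
    do.call(rbind, rows)
}

#' Run the full diagnostic-accuracy workflow
#'
#' Orchestrates the study analysis on a cohort: (1) preprocessing
#' (transforms + outlier exclusion); (2) per-marker single-marker latent
#' class fits, accuracy tables and ROC curves; (3) provisional labels by
#' majority vote of the single-marker classifications, then covariate
#' screening at \code{screenAlpha}; (4) multivariate fits for every
#' pairwise and the full marker combination, without covariates and — when
#' any covariate survives screening — with the selected covariates; (5)
#' combined accuracy tables and cROC curves, a final classification from
#' the covariate-adjusted full combination (falling back to the unadjusted
#' one), and the group-comparison table. All tables are written as CSV
#' under \code{outDir} together with a JSON manifest and diagnostics;
#' everything is driven by one seed, so a fixed seed reproduces the bundle
#' byte for byte.
#'
#' @param cohort a \linkS4class{MarkerCohort}
#' @param outDir output directory (created if needed); NULL returns results
#'   without writing
#' @param transforms per-marker transforms for preprocessing
#' @param outlierRule,multiplier see \code{\link{preprocessCohort}}
#' @param screenAlpha covariate screening level (default 0.20)
#' @param singleSettings,combinedSettings \linkS4class{MCMCSettings} for the
#'   two model families
#' @param priors a \linkS4class{PriorSpec} for the single-marker fits (the
#'   combined fits use N(0, 100) coefficient priors)
#' @param anchor anchor marker for the combined fits
#' @param seed master seed; per-model seeds are derived deterministically
#' @return (invisibly) a list with the preprocessed cohort, fits, accuracy
#'   tables, screening result, classification and comparison table
#' @export
runPipeline <- function(cohort, outDir = NULL, transforms = character(),
                        outlierRule = "robust-z", multiplier = 3,
                        screenAlpha = 0.20,
                        singleSettings = mcmcSettings(),
                        combinedSettings = combinedMCMCSettings(),
                        priors = priorSpec(), anchor = NULL, seed = 1L) {
    stage <- "preprocess"
    result <- tryCatch({
        pre <- preprocessCohort(cohort, transforms = transforms,
                                outlierRule = outlierRule,
                                multiplier = multiplier)
        m <- markerMatrix(pre)
        markers <- colnames(m)

        stage <- "fit-single"
        singles <- list(); singleAcc <- list(); rocs <- list()
        votes <- matrix(0L, nrow(m), length(markers))
        for (j in seq_along(markers)) {
            st <- singleSettings
            st@seed <- as.integer((seed + 1000L * j) %% .Machine$integer.max)
            fit <- fitSingleMarkerLCM(m[, j], priors = priors, settings = st)
            singles[[markers[j]]] <- fit
            singleAcc[[markers[j]]] <- singleAccuracySummary(fit)
            pm <- colMeans(posteriorDraws(fit))
            rocs[[markers[j]]] <- rocCurve(pm["muPos"], pm["varPos"],
                                           pm["muNeg"], pm["varNeg"])
            votes[, j] <- as.integer(classProbabilities(fit) >= 0.5)
        }
        provisional <- as.integer(rowMeans(votes) > 0.5)

        stage <- "screen-covariates"
        cov <- as.data.frame(covariateTable(pre))
        selected <- if (ncol(cov))
            screenCovariates(pre, labels = provisional, alpha = screenAlpha)
        else character()
        X <- if (length(selected))
            encodeCovariates(cov[selected], standardize = TRUE)
        else NULL

        stage <- "fit-combined"
        combos <- c(if (length(markers) > 2) utils::combn(markers, 2,
                                                          simplify = FALSE),
                    list(markers))
        comboName <- vapply(combos, paste, "", collapse = "+")
        combined <- list(); combinedAcc <- list(); crocs <- list()
        for (ci in seq_along(combos)) {
            mk <- combos[[ci]]
            for (adj in c(FALSE, TRUE)) {
                if (adj && is.null(X)) next
                st <- combinedSettings
                st@seed <- as.integer((seed + 5000L * ci + adj) %%
                                      .Machine$integer.max)
                fit <- fitCombinedLCM(m[, mk, drop = FALSE],
                                      X = if (adj) X else NULL,
                                      settings = st, anchor = anchor)
                key <- paste0(comboName[ci], if (adj) " (adjusted)")
                combined[[key]] <- fit
                combinedAcc[[key]] <- combinedAccuracySummary(fit)
                pm <- colMeans(posteriorDraws(fit))
                # posterior-mean parameters for the point cROC curve
                meanFit <- fit
                meanFit@posterior@draws[1, ] <- pm
                pp <- .unpackCombinedDraw(meanFit, 1)
                x0 <- numeric(length(pp$alpha) - 1)
                w <- combinationWeights(meanStructure(pp$B, x0, 1),
                                        meanStructure(pp$B, x0, 0),
                                        pp$sigma0, pp$sigma1)
                crocs[[key]] <- combinedRocCurve(w, pp$sigma0, pp$sigma1)
            }
        }

        stage <- "classify"
        finalKey <- if (!is.null(X))
            paste0(comboName[length(combos)], " (adjusted)")
        else comboName[length(combos)]
        cls <- classifySubjects(combined[[finalKey]])

        stage <- "compare-groups"
        comparison <- if (all(c(0L, 1L) %in% cls$assignment))
            compareGroups(pre, cls$assignment) else NULL

        list(cohort = pre, singleFits = singles,
             singleAccuracy = singleAcc, rocCurves = rocs,
             provisionalLabels = provisional,
             selectedCovariates = selected,
             combinedFits = combined, combinedAccuracy = combinedAcc,
             combinedRocCurves = crocs, finalModel = finalKey,
             classification = cls, comparison = comparison, seed = seed)
    }, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))

    if (!is.null(outDir)) .writePipelineBundle(result, outDir)
    invisible(result)
}

# write the report bundle: CSV tables, ROC curves, diagnostics, manifest
.writePipelineBundle <- function(result, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name)
        utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
    accRows <- function(nm, acc) cbind(model = nm, cutoff = acc$cutoff,
                                       acc$table)
    singleTab <- do.call(rbind, Map(accRows, names(result$singleAccuracy),
                                    result$singleAccuracy))
    wcsv(singleTab, "accuracy_single.csv")
    adj <- grepl("\\(adjusted\\)$", names(result$combinedAccuracy))
    if (any(!adj))
        wcsv(do.call(rbind, Map(accRows,
                                names(result$combinedAccuracy)[!adj],
                                result$combinedAccuracy[!adj])),
             "accuracy_combined_unadjusted.csv")
    if (any(adj))
        wcsv(do.call(rbind, Map(accRows,
                                names(result$combinedAccuracy)[adj],
                                result$combinedAccuracy[adj])),
             "accuracy_combined_adjusted.csv")
    for (nm in names(result$rocCurves))
        wcsv(result$rocCurves[[nm]],
             paste0("roc_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    for (nm in names(result$combinedRocCurves))
        wcsv(result$combinedRocCurves[[nm]],
             paste0("croc_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    cls <- data.frame(subject_id = subjectIds(result$cohort),
                      probability = result$classification$probability,
                      assignment = result$classification$assignment)
    wcsv(cls, "classification.csv")
    if (!is.null(result$comparison))
        wcsv(result$comparison, "group_comparison.csv")
    excl <- metadata(result$cohort)$exclusions
    if (!is.null(excl)) wcsv(excl, "exclusions.csv")
    diag <- lapply(result$singleFits, function(f)
        summarizeDraws(f)[, c("parameter", "gewekeZ", "lag1Autocorr")])
    jsonlite::write_json(diag, file.path(outDir, "diagnostics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest <- list(
        seed = result$seed,
        n = ncol(result$cohort),
        markers = colnames(markerMatrix(result$cohort)),
        selectedCovariates = result$selectedCovariates,
        finalModel = result$finalModel,
        groupSizes = as.list(result$classification$groupSizes),
        packageVersion =
            as.character(utils::packageVersion("lcmROC")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}
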