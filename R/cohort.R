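#' Construct a MarkerCohort
#'
#' @param markers numeric matrix (n subjects x k markers) with column names.
#' @param covariates data.frame/DataFrame of covariates, n rows, or NULL.
#'   Character columns are converted to factors; factor level order is taken
#'   from the column (first level = reference for later dummy encoding).
#' @param subjectIds character vector of ids (default \code{S1..Sn}).
#' @param trueLabels optional 0/1 vector of latent disease labels (synthetic
#'   cohorts only).
#' @return a \linkS4class{MarkerCohort}
#' @examples
#' y <- cbind(LDH = rnorm(5, 2.6, 0.1), Cr = rnorm(5, 0.9, 0.15))
#' cov <- data.frame(age = c(30, 41, 35, 28, 50))
#' MarkerCohort(y, cov)
#' @export
MarkerCohort <- function(markers, covariates = NULL, subjectIds = NULL,
                         trueLabels = NULL) {
    markers <- as.matrix(markers)
    if (is.null(colnames(markers)))
        colnames(markers) <- paste0("M", seq_len(ncol(markers)))
    n <- nrow(markers)
    if (n < 1L) stop("a cohort needs at least one subject")
    if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(n))
    if (anyDuplicated(subjectIds)) stop("subject ids must be unique")
    cd <- if (is.null(covariates)) DataFrame(row.names = subjectIds)
          else {
              covariates <- as.data.frame(covariates)
              if (nrow(covariates) != n)
                  stop("covariates and markers must have equal row counts")
              for (j in seq_along(covariates))
                  if (is.character(covariates[[j]]))
                      covariates[[j]] <- factor(covariates[[j]])
              DataFrame(covariates, row.names = subjectIds)
          }
    covNames <- colnames(cd)
    if (!is.null(trueLabels)) {
        if (length(trueLabels) != n)
            stop("trueLabels must have one entry per subject")
        if (!all(trueLabels %in% c(0, 1)))
            stop("trueLabels must be 0/1")
        cd$.trueLabel <- as.integer(trueLabels)
    }
    se <- SummarizedExperiment(
        assays = list(markers = t(markers)), colData = cd)
    colnames(se) <- subjectIds
    new("MarkerCohort", se, covariateNames = covNames)
}

#' Read a cohort from a delimited text file
#'
#' @param path path to a CSV/TSV file with a header row, one subject per row.
#' @param markerCols character vector naming the marker columns (must be
#'   numeric in the file).
#' @param covariateCols character vector naming covariate columns; columns
#'   listed in \code{categoricalCols} (or non-numeric columns) become factors.
#' @param idCol optional name of a subject-id column.
#' @param labelCol optional name of a 0/1 true-label column.
#' @param categoricalCols covariate columns to force to factors, optionally a
#'   named list of level vectors to fix level order.
#' @param sep field separator; \code{""} guesses from the file extension
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @return a \linkS4class{MarkerCohort}
#' @export
readCohort <- function(path, markerCols, covariateCols = character(),
                       idCol = NULL, labelCol = NULL,
                       categoricalCols = character(), sep = "") {
    if (!file.exists(path)) stop("no such file: ", path)
    if (identical(sep, ""))
        sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    declared <- c(markerCols, covariateCols, idCol, labelCol)
    missing <- setdiff(declared, colnames(df))
    if (length(missing))
        stop("schema error: declared column(s) absent from file: ",
             paste(missing, collapse = ", "))
    for (mc in markerCols) {
        v <- df[[mc]]
        if (is.character(v)) {
            num <- suppressWarnings(as.numeric(v))
            bad <- which(is.na(num) & !is.na(v))
            if (length(bad))
                stop(sprintf("parse error: non-numeric value '%s' in marker column '%s' at row %d",
                             v[bad[1]], mc, bad[1]))
            df[[mc]] <- num
        }
        if (!is.numeric(df[[mc]]))
            stop("parse error: marker column '", mc, "' is not numeric")
    }
    catNames <- if (is.list(categoricalCols)) names(categoricalCols)
                else categoricalCols
    cov <- if (length(covariateCols)) df[covariateCols] else NULL
    if (!is.null(cov))
        for (cc in intersect(catNames, covariateCols)) {
            lv <- if (is.list(categoricalCols)) categoricalCols[[cc]] else NULL
            cov[[cc]] <- if (is.null(lv)) factor(cov[[cc]])
                         else {
                             bad <- setdiff(unique(as.character(cov[[cc]])), lv)
                             if (length(bad))
                                 stop("value(s) outside declared levels for '",
                                      cc, "': ", paste(bad, collapse = ", "))
                             factor(cov[[cc]], levels = lv)
                         }
        }
    ids <- if (is.null(idCol)) NULL else as.character(df[[idCol]])
    labels <- if (is.null(labelCol)) NULL else df[[labelCol]]
    MarkerCohort(as.matrix(df[markerCols]), covariates = cov,
                 subjectIds = ids, trueLabels = labels)
}

#' Read a cohort using a YAML schema file
#'
#' The schema file holds the \code{\link{readCohort}} arguments, e.g.
#' \preformatted{
#' markerCols: [LDH, UA, Cr]
#' covariateCols: [age, sex]
#' categoricalCols: [sex]
#' idCol: subject_id
#' }
#'
#' @param path cohort file path
#' @param schemaPath YAML schema file path
#' @return a \linkS4class{MarkerCohort}
#' @export
readCohortWithSchema <- function(path, schemaPath) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for schema files")
    schema <- yaml::read_yaml(schemaPath)
    known <- setdiff(names(formals(readCohort)), "path")
    bad <- setdiff(names(schema), known)
    if (length(bad))
        stop("schema error: unknown field(s): ", paste(bad, collapse = ", "))
    do.call(readCohort, c(list(path = path), schema))
}

#' Write a cohort to a delimited text file
#'
#' Columns: \code{subject_id}, the markers, the covariates, and
#' \code{true_label} when present. \code{readCohort} on the result restores
#' the cohort (full printed precision, 15 significant digits).
#'
#' @param x a \linkS4class{MarkerCohort}
#' @param path output file path (extension selects the separator as in
#'   \code{readCohort})
#' @return \code{path}, invisibly
#' @export
writeCohort <- function(x, path) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    df <- data.frame(subject_id = subjectIds(x), check.names = FALSE)
    m <- markerMatrix(x)
    for (j in colnames(m)) df[[j]] <- m[, j]
    cov <- as.data.frame(covariateTable(x))
    for (j in colnames(cov)) df[[j]] <- cov[[j]]
    tl <- trueLabels(x)
    if (!is.null(tl)) df$true_label <- tl
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) format(v, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Preprocess a cohort: per-marker transforms and robust outlier exclusion
#'
#' Applies per-marker transforms (currently \code{"none"} or \code{"log10"}),
#' then excludes any subject with a marker value outside
#' median +/- multiplier * (IQR / 1.349) on the analysis (post-transform)
#' scale; IQR/1.349 is the normal-consistent robust sigma estimate. Subjects
#' with missing marker or covariate values are excluded with a logged reason.
#' The exclusion log (subject id + reason) is stored in
#' \code{metadata(result)$exclusions}.
#'
#' @param x a \linkS4class{MarkerCohort}
#' @param transforms named character vector, \code{c(LDH = "log10")};
#'   unlisted markers are left untouched.
#' @param outlierRule \code{"robust-z"} (default) or \code{"none"}.
#' @param multiplier robust-z multiplier (default 3).
#' @return a preprocessed \linkS4class{MarkerCohort}
#' @examples
#' y <- cbind(LDH = c(100, 120, 1e5), Cr = c(0.9, 1.0, 1.1))
#' x <- MarkerCohort(y)
#' preprocessCohort(x, transforms = c(LDH = "log10"))
#' @export
preprocessCohort <- function(x, transforms = character(),
                             outlierRule = c("robust-z", "none"),
                             multiplier = 3) {
    outlierRule <- match.arg(outlierRule)
    m <- markerMatrix(x)
    bad <- setdiff(names(transforms), colnames(m))
    if (length(bad))
        stop("transform names not among markers: ", paste(bad, collapse = ", "))
    for (mk in names(transforms)) {
        tr <- match.arg(transforms[[mk]], c("none", "log10"))
        if (tr == "log10") {
            nonpos <- which(m[, mk] <= 0)
            if (length(nonpos))
                stop(sprintf("log10 transform of non-positive value in marker '%s' at row %d (subject %s)",
                             mk, nonpos[1], subjectIds(x)[nonpos[1]]))
            m[, mk] <- log10(m[, mk])
        }
    }
    ids <- subjectIds(x)
    reason <- rep(NA_character_, nrow(m))
    miss <- which(rowSums(is.na(m)) > 0)
    reason[miss] <- "missing marker value"
    cov <- as.data.frame(covariateTable(x))
    if (ncol(cov)) {
        cmiss <- which(rowSums(is.na(cov)) > 0)
        reason[cmiss[is.na(reason[cmiss])]] <- "missing covariate value"
    }
    if (outlierRule == "robust-z") {
        ok <- is.na(reason)
        for (j in seq_len(ncol(m))) {
            med <- stats::median(m[ok, j])
            sig <- stats::IQR(m[ok, j]) / 1.349
            if (sig == 0) next
            out <- which(abs(m[, j] - med) > multiplier * sig & is.na(reason))
            reason[out] <- sprintf("outlier in %s (robust z > %g)",
                                   colnames(m)[j], multiplier)
        }
    }
    keep <- is.na(reason)
    if (!any(keep)) stop("preprocessing excluded every subject")
    log <- data.frame(subject_id = ids[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
    out <- MarkerCohort(m[keep, , drop = FALSE],
                        covariates = if (ncol(cov)) cov[keep, , drop = FALSE]
                                     else NULL,
                        subjectIds = ids[keep],
                        trueLabels = trueLabels(x)[keep])
    metadata(out)$exclusions <- log
    metadata(out)$transforms <- transforms
    out
}

#' Dummy-encode and standardize the covariates of a cohort
#'
#' Continuous covariates are z-scored; categorical covariates become
#' reference-level dummy columns (first declared level = reference), in the
#' order the columns are declared. The applied transform is recorded in
#' attribute \code{"transform"} so fitted coefficients can be mapped back.
#'
#' @param x a \linkS4class{MarkerCohort} or data.frame of covariates
#' @param standardize z-score continuous columns (default TRUE)
#' @return numeric design matrix without intercept, with attribute
#'   \code{"transform"} (list of per-column centre/scale or levels)
#' @export
encodeCovariates <- function(x, standardize = TRUE) {
    cov <- if (is(x, "MarkerCohort")) as.data.frame(covariateTable(x))
           else as.data.frame(x)
    if (!ncol(cov)) {
        out <- matrix(numeric(0), nrow = nrow(cov), ncol = 0)
        attr(out, "transform") <- list()
        return(out)
    }
    cols <- list(); transform <- list()
    for (j in colnames(cov)) {
        v <- cov[[j]]
        if (is.numeric(v)) {
            ctr <- if (standardize) mean(v) else 0
            scl <- if (standardize && stats::sd(v) > 0) stats::sd(v) else 1
            cols[[j]] <- (v - ctr) / scl
            transform[[j]] <- list(type = "continuous", center = ctr,
                                   scale = scl)
        } else {
            v <- if (is.factor(v)) v else factor(v)
            lv <- levels(v)
            for (l in lv[-1])
                cols[[paste0(j, ".", l)]] <- as.numeric(v == l)
            transform[[j]] <- list(type = "categorical", levels = lv)
        }
    }
    out <- do.call(cbind, cols)
    rownames(out) <- rownames(cov)
    attr(out, "transform") <- transform
    out
}
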