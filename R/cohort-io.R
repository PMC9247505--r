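#' @include cohort-class.R
NULL

.META_COLS <- c("subject_id", "center_id", "diagnosis",
                "age", "sex", "education", "icv")

#' Read a multicenter thickness table
#'
#' Reads a delimited text table (comma-separated by default; UTF-8, `.`
#' decimal) with one row per scan: the metadata columns `subject_id`,
#' `center_id`, `diagnosis`, `age`, `sex`, `education`, `icv`, and one
#' numeric column per ROI. Every non-metadata column is taken as an ROI, in
#' file order. Rows violating the invariants (non-positive or non-finite
#' thickness, age or ICV; invalid diagnosis; sex not 0/1) are dropped with a
#' warning naming the offending rows.
#'
#' @param path File to read.
#' @param schema Optional named character vector mapping the standard
#'   metadata names to the file's column names, e.g.
#'   `c(subject_id = "ID", icv = "eTIV")`.
#' @param sep Field separator; use `"\t"` for TSV.
#' @param eduPolicy Missing-education handling: `"keep"` (default; models
#'   apply their own fit/score-time policy), `"drop"` (drop the row), or
#'   `"impute"` (cohort CN median).
#' @return A [CohortExperiment].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, schema = NULL, sep = ",",
                       eduPolicy = c("keep", "drop", "impute")) {
    eduPolicy <- match.arg(eduPolicy)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", encoding = "UTF-8")
    if (!is.null(schema)) {
        for (std in names(schema)) {
            j <- match(schema[[std]], names(df))
            if (is.na(j)) {
                stop(sprintf("schema column '%s' (for '%s') not in file",
                             schema[[std]], std))
            }
            names(df)[j] <- std
        }
    }
    miss <- setdiff(.META_COLS, names(df))
    if (length(miss)) {
        stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    }
    roiCols <- setdiff(names(df), .META_COLS)
    if (!length(roiCols)) stop("no ROI columns found")

    numify <- function(col, what) {
        x <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(x) & !is.na(df[[col]]) &
                         !(df[[col]] %in% c("", "NA")))
        if (length(bad)) {
            stop(sprintf("non-numeric %s in column '%s' at row(s) %s",
                         what, col,
                         paste(utils::head(bad, 5L), collapse = ", ")))
        }
        x
    }
    th <- vapply(roiCols, numify, numeric(nrow(df)), what = "thickness")
    if (nrow(df) == 1L) th <- matrix(th, 1L, dimnames = list(NULL, roiCols))
    age <- numify("age", "covariate")
    sex <- numify("sex", "covariate")
    edu <- numify("education", "covariate")
    icv <- numify("icv", "covariate")
    dx <- df$diagnosis

    ok <- rep(TRUE, nrow(df))
    if (nrow(df)) {
        thOk <- apply(th, 1L, function(r) all(is.finite(r) & r > 0))
        ok <- thOk & is.finite(age) & age > 0 & sex %in% c(0, 1) &
            is.finite(icv) & icv > 0 & dx %in% .DIAGNOSIS_LEVELS
    }
    if (any(!ok)) {
        warning(sprintf("rejecting %d invalid row(s): %s",
                        sum(!ok),
                        paste(utils::head(which(!ok), 10L), collapse = ", ")))
    }
    keep <- which(ok)
    if (eduPolicy == "drop") keep <- keep[!is.na(edu[keep])]
    if (eduPolicy == "impute" && any(is.na(edu[keep]))) {
        cnEdu <- edu[keep][dx[keep] == "CN" & !is.na(edu[keep])]
        edu[keep][is.na(edu[keep])] <- stats::median(cnEdu)
    }
    CohortExperiment(th[keep, , drop = FALSE],
                     subject_id = df$subject_id[keep],
                     center_id = df$center_id[keep],
                     diagnosis = dx[keep], age = age[keep], sex = sex[keep],
                     education = edu[keep], icv = icv[keep])
}

#' Write a cohort or w-score table
#'
#' Columns are written in a deterministic order (metadata first, then ROIs in
#' container order) at full double precision, so that
#' `readCohort(writeCohort(x))` reproduces `x` exactly.
#'
#' @param x A [CohortExperiment] or [WScoreExperiment].
#' @param path File to write.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
writeCohort <- function(x, path, sep = ",") {
    mat <- if (methods::is(x, "WScoreExperiment")) {
        wscoreMatrix(x)
    } else {
        thicknessMatrix(x)
    }
    cd <- SummarizedExperiment::colData(x)
    fmt <- function(v) {
        out <- sprintf("%.17g", v)
        out[is.na(v)] <- "NA"
        out
    }
    df <- data.frame(subject_id = as.character(cd$subject_id),
                     center_id = as.character(cd$center_id),
                     diagnosis = as.character(cd$diagnosis),
                     age = fmt(cd$age), sex = fmt(cd$sex),
                     education = fmt(cd$education), icv = fmt(cd$icv),
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (k in colnames(mat)) df[[k]] <- fmt(mat[, k])
    ok <- tryCatch({
        utils::write.table(df, path, sep = sep, quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
        TRUE
    }, error = function(e) stop("cannot write '", path, "': ",
                                conditionMessage(e)))
    invisible(path)
}
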