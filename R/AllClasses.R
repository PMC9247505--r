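#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.DIAGNOSIS_LEVELS <- c("CN", "AD", "PD", "OTHER", "UNKNOWN")
.COVARIATE_NAMES <- c("age", "sex", "education", "icv")
.MODEL_FORMAT_VERSION <- 1L

#' Multicenter cortical-thickness cohort
#'
#' A `CohortExperiment` stores one scan per column: a thickness assay
#' (ROIs x scans, mm) plus per-scan metadata in `colData`: `subject_id`,
#' `center_id` (the dataset indicator), `diagnosis` (CN/AD/PD/OTHER/UNKNOWN),
#' and the biological covariates `age` (years), `sex` (0 = female, 1 = male),
#' `education` (years, `NA` allowed), `icv` (mm^3). The same `subject_id` may
#' appear under two centers (paired intrasubject designs); a scan is
#' identified by the (subject, center) pair.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [CohortExperiment()], [readCohort()], [generateCohort()]
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

#' Harmonized w-score container
#'
#' Same shape and scan metadata as the source [CohortExperiment], with a
#' single `wscore` assay of dimensionless standardized scores.
#'
#' @seealso [harmonize()]
#' @export
setClass("WScoreExperiment", contains = "SummarizedExperiment")

.validCohortLike <- function(object, assayName, positive) {
    msg <- character()
    if (!(assayName %in% SummarizedExperiment::assayNames(object))) {
        return(sprintf("assay '%s' is required", assayName))
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("subject_id", "center_id", "diagnosis", .COVARIATE_NAMES)
    miss <- setdiff(need, colnames(cd))
    if (length(miss)) {
        return(sprintf("missing colData column(s): %s",
                       paste(miss, collapse = ", ")))
    }
    if (nrow(object) < 1L) msg <- c(msg, "at least one ROI is required")
    if (ncol(object)) {
        dx <- as.character(cd$diagnosis)
        bad <- !dx %in% .DIAGNOSIS_LEVELS
        if (any(bad)) {
            msg <- c(msg, sprintf("invalid diagnosis value(s): %s",
                                  paste(unique(dx[bad]), collapse = ", ")))
        }
        if (!all(is.finite(cd$age)) || any(cd$age <= 0)) {
            msg <- c(msg, "age must be finite and > 0")
        }
        if (!all(cd$sex %in% c(0, 1))) {
            msg <- c(msg, "sex must be coded 0 (female) / 1 (male)")
        }
        if (!all(is.finite(cd$icv)) || any(cd$icv <= 0)) {
            msg <- c(msg, "icv must be finite and > 0 (mm^3)")
        }
        edu <- cd$education
        if (!all(is.finite(edu) | is.na(edu))) {
            msg <- c(msg, "education must be finite or NA")
        }
        y <- SummarizedExperiment::assay(object, assayName)
        if (!all(is.finite(y))) {
            msg <- c(msg, sprintf("%s values must all be finite", assayName))
        } else if (positive && any(y <= 0)) {
            msg <- c(msg, sprintf("%s values must be > 0", assayName))
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
        msg <- c(msg, "ROI names must be present and unique")
    }
    if (length(msg)) msg else TRUE
}

setValidity("CohortExperiment", function(object) {
    .validCohortLike(object, "thickness", positive = TRUE)
})

setValidity("WScoreExperiment", function(object) {
    .validCohortLike(object, "wscore", positive = FALSE)
})

#' Protocol-specific (per-dataset) w-score model
#'
#' One robust regression of thickness on covariates per (center, ROI),
#' fitted on each center's cognitively normal scans; the w-score is the
#' residual standardized by the CN residual SD of that center and ROI.
#'
#' @slot roiNames character, ROI order.
#' @slot covariateNames character, covariate order.
#' @slot alpha numeric matrix centers x ROIs, intercepts (mm).
#' @slot beta numeric array centers x covariates x ROIs (mm per unit).
#' @slot residSd numeric matrix centers x ROIs, CN residual SD (mm).
#' @slot centers data.frame: center id, number of CN scans used.
#' @slot eduMedians named numeric, per-center CN education medians (plus
#'   `.global`), used to impute missing education at scoring time.
#' @export
setClass("SelfWModel", representation(
    roiNames = "character",
    covariateNames = "character",
    alpha = "matrix",
    beta = "array",
    residSd = "matrix",
    centers = "data.frame",
    eduMedians = "numeric",
    version = "integer"
))

#' ComBat location/scale harmonization model
#'
#' Pooled covariate regression plus per-center additive (`gamma*`) and
#' multiplicative (`delta*`) batch effects on the standardized scale,
#' shrunk by parametric empirical Bayes (normal prior on gamma,
#' inverse-gamma prior on delta^2).
#'
#' @slot alpha numeric, grand intercept per ROI (mm).
#' @slot beta numeric matrix covariates x ROIs (mm per unit).
#' @slot pooledSd numeric, per-ROI standardization scale (mm).
#' @slot gammaStar,deltaStar numeric matrices centers x ROIs (dimensionless;
#'   `deltaStar` > 0 is the residual SD inflation of the center).
#' @slot hyper data.frame of per-center EB hyperparameters
#'   (gamma_bar, tau2, lambda, theta).
#' @export
setClass("ComBatModel", representation(
    roiNames = "character",
    covariateNames = "character",
    alpha = "numeric",
    beta = "matrix",
    pooledSd = "numeric",
    gammaStar = "matrix",
    deltaStar = "matrix",
    hyper = "data.frame",
    centers = "data.frame",
    eduMedians = "numeric",
    version = "integer"
))

#' Linear mixed-effects w-score model
#'
#' Per ROI: fixed effects (intercept + biological covariates), a random
#' center intercept with variance `d` (exchangeable across centers),
#' residual variance `sigma2`, per-center BLUP intercepts `b`, and the
#' pooled CN residual SD `s` used to standardize w-scores. Fitted by ReML;
#' centers can be scored via their BLUP, via the marginal mean (unseen
#' centers), or registered later with frozen parameters ([addCenter()]).
#'
#' @slot alpha numeric per ROI (mm).
#' @slot beta numeric matrix covariates x ROIs (mm per covariate unit).
#' @slot d numeric per ROI, random-intercept variance (mm^2).
#' @slot sigma2 numeric per ROI, residual variance (mm^2).
#' @slot b numeric matrix centers x ROIs, predicted center intercepts (mm).
#' @slot s numeric per ROI, pooled CN residual SD (mm).
#' @slot betaCov numeric array (p+1) x (p+1) x ROIs, model-based covariance
#'   of (alpha, beta) from the GLS information matrix.
#' @slot centers data.frame: center id, n CN used, whether added post hoc.
#' @slot diagnostics list: convergence flags, final restricted
#'   log-likelihood per ROI, optimizer multi-start table.
#' @export
setClass("LMEModel", representation(
    roiNames = "character",
    covariateNames = "character",
    alpha = "numeric",
    beta = "matrix",
    d = "numeric",
    sigma2 = "numeric",
    b = "matrix",
    s = "numeric",
    betaCov = "array",
    centers = "data.frame",
    eduMedians = "numeric",
    diagnostics = "list",
    version = "integer"
))

setValidity("SelfWModel", function(object) {
    if (any(object@residSd <= 0, na.rm = TRUE)) {
        return("residSd must be > 0 for fitted centers")
    }
    TRUE
})

setValidity("ComBatModel", function(object) {
    if (any(object@deltaStar <= 0)) return("deltaStar must be > 0")
    if (any(object@pooledSd <= 0)) return("pooledSd must be > 0")
    TRUE
})

setValidity("LMEModel", function(object) {
    msg <- character()
    if (any(object@d < 0)) msg <- c(msg, "d must be >= 0")
    if (any(object@sigma2 <= 0)) msg <- c(msg, "sigma2 must be > 0")
    if (any(object@s <= 0)) msg <- c(msg, "s must be > 0")
    if (length(msg)) msg else TRUE
})
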