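#' @include AllClasses.R
NULL

#' Subject identifiers of a cohort
#'
#' @param x A [CohortExperiment] or [WScoreExperiment].
#' @return Character vector, one entry per scan.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Center (dataset) identifiers of a cohort
#'
#' @param x A [CohortExperiment] or [WScoreExperiment].
#' @return Character vector, one entry per scan.
#' @export
setGeneric("centerIds", function(x) standardGeneric("centerIds"))

#' Diagnosis labels of a cohort
#'
#' @param x A [CohortExperiment] or [WScoreExperiment].
#' @return Factor with levels `CN`, `AD`, `PD`, `OTHER`, `UNKNOWN`.
#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))

#' Biological covariate matrix
#'
#' Covariates enter all models in raw units: age (years), sex (0 = female,
#' 1 = male), education (years, possibly `NA`), intracranial volume (mm^3).
#'
#' @param x A [CohortExperiment] or [WScoreExperiment].
#' @return Numeric matrix, scans in rows, columns
#'   `age`, `sex`, `education`, `icv`.
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' Thickness matrix (scans in rows)
#'
#' @param x A [CohortExperiment].
#' @return Numeric matrix, scans x ROIs, in mm.
#' @export
setGeneric("thicknessMatrix", function(x) standardGeneric("thicknessMatrix"))

#' W-score matrix (scans in rows)
#'
#' @param x A [WScoreExperiment].
#' @return Numeric matrix of dimensionless standardized scores, scans x ROIs.
#' @export
setGeneric("wscoreMatrix", function(x) standardGeneric("wscoreMatrix"))

#' ROI names
#'
#' @param x A cohort, w-score container, or fitted harmonization model.
#' @return Character vector of region names.
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Centers known to a fitted harmonization model
#'
#' @param object A fitted [SelfWModel], [ComBatModel] or [LMEModel].
#' @return Character vector of center ids registered at fit (or update) time.
#' @export
setGeneric("modelCenters", function(object) standardGeneric("modelCenters"))

#' Apply a fitted harmonization model to a cohort
#'
#' For [SelfWModel] and [LMEModel] the result is a [WScoreExperiment] of
#' standardized w-scores; for [ComBatModel] the result is a
#' [CohortExperiment] whose thickness has been batch-adjusted (ComBat returns
#' harmonized thickness in mm, not a standardized score).
#'
#' @param object A fitted harmonization model.
#' @param cohort A [CohortExperiment] to score.
#' @param ... Method-specific arguments; see [scoreLME()], [scoreSelfW()],
#'   [applyComBat()].
#' @return A [WScoreExperiment] or [CohortExperiment], same scans and ROI
#'   order as `cohort`.
#' @export
setGeneric("harmonize", function(object, cohort, ...) {
    standardGeneric("harmonize")
})

#' Register a new center in a fitted model without refitting
#'
#' @param object A fitted model supporting incremental center registration.
#' @param newData A [CohortExperiment] holding the new center's reference
#'   (cognitively normal) scans.
#' @param ... Method-specific arguments.
#' @return An updated model; existing centers' scores are unchanged.
#' @export
setGeneric("addCenter", function(object, newData, ...) {
    standardGeneric("addCenter")
})

#' Serialize a fitted harmonization model to JSON
#'
#' @param object A fitted [SelfWModel], [ComBatModel] or [LMEModel].
#' @param path File path to write.
#' @return Invisibly, `path`. A model reloaded with [loadModel()] scores
#'   identically to the in-memory model.
#' @export
setGeneric("saveModel", function(object, path) standardGeneric("saveModel"))
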