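#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CohortExperiment
#'
#' @param thickness Numeric matrix of mean regional thickness in mm, scans in
#'   rows and ROIs in columns (column names are the ROI names; defaults to the
#'   68 Desikan-Killiany names when the matrix has 68 unnamed columns).
#' @param subject_id,center_id Character vectors, one entry per scan.
#' @param diagnosis Character or factor; one of `CN`, `AD`, `PD`, `OTHER`,
#'   `UNKNOWN`.
#' @param age Age in years.
#' @param sex 0 = female, 1 = male.
#' @param education Years of education; `NA` allowed.
#' @param icv Intracranial volume in mm^3.
#' @return A validated [CohortExperiment].
#' @examples
#' th <- matrix(2.5, 2, 68)
#' coh <- CohortExperiment(th, subject_id = c("s1", "s2"),
#'     center_id = "D1", diagnosis = "CN", age = c(70, 75), sex = c(0, 1),
#'     education = 12, icv = 1.4e6)
#' @export
CohortExperiment <- function(thickness, subject_id, center_id, diagnosis,
                             age, sex, education = NA_real_, icv) {
    thickness <- as.matrix(thickness)
    n <- nrow(thickness)
    if (is.null(colnames(thickness))) {
        if (ncol(thickness) == 68L) {
            colnames(thickness) <- dkRoiNames()
        } else {
            colnames(thickness) <- sprintf("roi%02d", seq_len(ncol(thickness)))
        }
    }
    cd <- S4Vectors::DataFrame(
        subject_id = rep_len(as.character(subject_id), n),
        center_id = rep_len(as.character(center_id), n),
        diagnosis = factor(rep_len(as.character(diagnosis), n),
                           levels = .DIAGNOSIS_LEVELS),
        age = rep_len(as.numeric(age), n),
        sex = rep_len(as.numeric(sex), n),
        education = rep_len(as.numeric(education), n),
        icv = rep_len(as.numeric(icv), n)
    )
    scan_id <- make.unique(paste(cd$subject_id, cd$center_id, sep = "."))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(thickness = t(thickness)),
        colData = cd
    )
    colnames(se) <- scan_id
    methods::validObject(out <- methods::new("CohortExperiment", se))
    out
}

.newWScoreExperiment <- function(cohort, wmat) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(wscore = t(wmat)),
        colData = SummarizedExperiment::colData(cohort)
    )
    colnames(se) <- colnames(cohort)
    methods::new("WScoreExperiment", se)
}

#' Standard Desikan-Killiany ROI names
#'
#' The 34 cortical parcels per hemisphere of the Desikan-Killiany atlas,
#' prefixed `lh_` / `rh_` (68 names).
#'
#' @return Character vector of length 68.
#' @export
dkRoiNames <- function() {
    base <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
              "cuneus", "entorhinal", "fusiform", "inferiorparietal",
              "inferiortemporal", "isthmuscingulate", "lateraloccipital",
              "lateralorbitofrontal", "lingual", "medialorbitofrontal",
              "middletemporal", "parahippocampal", "paracentral",
              "parsopercularis", "parsorbitalis", "parstriangularis",
              "pericalcarine", "postcentral", "posteriorcingulate",
              "precentral", "precuneus", "rostralanteriorcingulate",
              "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
              "superiortemporal", "supramarginal", "frontalpole",
              "temporalpole", "transversetemporal", "insula")
    c(paste0("lh_", base), paste0("rh_", base))
}

#' @rdname subjectIds
setMethod("subjectIds", "SummarizedExperiment", function(x) {
    as.character(SummarizedExperiment::colData(x)$subject_id)
})

#' @rdname centerIds
setMethod("centerIds", "SummarizedExperiment", function(x) {
    as.character(SummarizedExperiment::colData(x)$center_id)
})

#' @rdname diagnoses
setMethod("diagnoses", "SummarizedExperiment", function(x) {
    factor(as.character(SummarizedExperiment::colData(x)$diagnosis),
           levels = .DIAGNOSIS_LEVELS)
})

#' @rdname covariateMatrix
setMethod("covariateMatrix", "SummarizedExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- cbind(age = cd$age, sex = cd$sex, education = cd$education,
               icv = cd$icv)
    rownames(m) <- colnames(x)
    m
})

#' @rdname thicknessMatrix
setMethod("thicknessMatrix", "CohortExperiment", function(x) {
    t(SummarizedExperiment::assay(x, "thickness"))
})

#' @rdname wscoreMatrix
setMethod("wscoreMatrix", "WScoreExperiment", function(x) {
    t(SummarizedExperiment::assay(x, "wscore"))
})

#' @rdname roiNames
setMethod("roiNames", "SummarizedExperiment", function(x) rownames(x))

setMethod("show", "CohortExperiment", function(object) {
    dx <- table(diagnoses(object))
    cat(sprintf("CohortExperiment: %d scans x %d ROIs, %d center(s)\n",
                ncol(object), nrow(object),
                length(unique(centerIds(object)))))
    cat("  diagnosis:",
        paste(sprintf("%s=%d", names(dx), dx), collapse = " "), "\n")
})

setMethod("show", "WScoreExperiment", function(object) {
    cat(sprintf("WScoreExperiment: %d scans x %d ROIs, %d center(s)\n",
                ncol(object), nrow(object),
                length(unique(centerIds(object)))))
})

# Split scan indices by center, preserving first-appearance order of centers.
.splitByCenter <- function(cohort) {
    cid <- centerIds(cohort)
    split(seq_along(cid), factor(cid, levels = unique(cid)))
}

# Subset of CN scans.
.cnSubset <- function(cohort) {
    cohort[, diagnoses(cohort) == "CN"]
}

# Education handling. At fit time rows with NA education are dropped (with a
# warning); at score time NA education is imputed from the fitting cohort's
# per-center CN medians (global CN median for centers without one).
.eduMedians <- function(cohort) {
    cd <- SummarizedExperiment::colData(cohort)
    cn <- as.character(cd$diagnosis) == "CN" & !is.na(cd$education)
    out <- c(.global = stats::median(cd$education[cn]))
    if (any(cn)) {
        per <- tapply(cd$education[cn], cd$center_id[cn], stats::median)
        out <- c(out, per)
    }
    out
}

.imputeEducation <- function(X, center, eduMedians) {
    na <- is.na(X[, "education"])
    if (!any(na)) return(X)
    fill <- eduMedians[center[na]]
    fill[is.na(fill)] <- eduMedians[[".global"]]
    X[na, "education"] <- fill
    X
}

.dropNaEducation <- function(cohort, what) {
    na <- is.na(covariateMatrix(cohort)[, "education"])
    if (any(na)) {
        warning(sprintf(
            "%s: dropping %d scan(s) with missing education at fit time",
            what, sum(na)))
        cohort <- cohort[, !na]
    }
    cohort
}
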