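#' @include cohort-class.R
NULL

#' Fit protocol-specific w-score models
#'
#' For every (center, ROI) pair, regresses thickness on the four biological
#' covariates within that center's cognitively normal scans using
#' iteratively reweighted least squares (Tukey bisquare weights,
#' tuning constant 4.685, via [MASS::rlm()]); the standardization scale is
#' the unbiased SD of the CN residuals. Patients are never used in fitting.
#' Centers with fewer than `minCn` CN scans are skipped with a warning —
#' such centers cannot carry their own normative model, the key limitation
#' this family of harmonizers has for new centers.
#'
#' @param cohort A [CohortExperiment].
#' @param minCn Minimum CN scans per fitted center (default p + 2 = 6).
#' @param maxit Maximum IRLS iterations.
#' @return A [SelfWModel].
#' @seealso [scoreSelfW()]
#' @export
fitSelfW <- function(cohort, minCn = 6L, maxit = 50L) {
    cn <- .cnSubset(cohort)
    eduMed <- .eduMedians(cohort)
    cn <- .dropNaEducation(cn, "fitSelfW")
    idx <- .splitByCenter(cn)
    sizes <- lengths(idx)
    skip <- names(idx)[sizes < minCn]
    if (length(skip)) {
        warning("skipping center(s) with < ", minCn, " CN scans: ",
                paste(skip, collapse = ", "))
        idx <- idx[sizes >= minCn]
    }
    if (!length(idx)) stop("no center has enough CN scans to fit")
    rois <- roiNames(cn)
    K <- length(rois)
    p <- length(.COVARIATE_NAMES)
    J <- length(idx)
    alpha <- matrix(NA_real_, J, K, dimnames = list(names(idx), rois))
    residSd <- alpha
    beta <- array(NA_real_, c(J, p, K),
                  dimnames = list(names(idx), .COVARIATE_NAMES, rois))
    th <- thicknessMatrix(cn)
    X <- covariateMatrix(cn)
    for (j in seq_along(idx)) {
        rows <- idx[[j]]
        Xj <- X[rows, , drop = FALSE]
        for (k in seq_len(K)) {
            y <- th[rows, k]
            fit <- suppressWarnings(MASS::rlm(
                x = cbind(1, Xj), y = y, psi = MASS::psi.bisquare,
                c = 4.685, maxit = maxit))
            cf <- stats::coef(fit)
            alpha[j, k] <- cf[1L]
            beta[j, , k] <- cf[-1L]
            r <- y - cbind(1, Xj) %*% cf
            s <- stats::sd(r)
            if (!is.finite(s) || s <= 0) {
                stop(sprintf(
                    "zero residual variance for center '%s', ROI '%s'",
                    names(idx)[j], rois[k]))
            }
            residSd[j, k] <- s
        }
    }
    methods::new("SelfWModel", roiNames = rois,
                 covariateNames = .COVARIATE_NAMES,
                 alpha = alpha, beta = beta, residSd = residSd,
                 centers = data.frame(id = names(idx),
                                      n_cn = as.integer(lengths(idx)),
                                      stringsAsFactors = FALSE),
                 eduMedians = eduMed, version = .MODEL_FORMAT_VERSION)
}

#' Score a cohort with a protocol-specific w-score model
#'
#' w = (y - alpha_jk - X beta_jk) / s_jk per (center j, ROI k). Every scored
#' scan must come from a center fitted at training time; this harmonizer has
#' no way to score unseen centers.
#'
#' @param model A [SelfWModel].
#' @param cohort A [CohortExperiment].
#' @return A [WScoreExperiment].
#' @export
scoreSelfW <- function(model, cohort) {
    cid <- centerIds(cohort)
    unknown <- setdiff(unique(cid), model@centers$id)
    if (length(unknown)) {
        stop("cannot score scans from center(s) not fitted: ",
             paste(unknown, collapse = ", "),
             " (protocol-specific w-scores require a per-center model)")
    }
    if (!identical(roiNames(cohort), model@roiNames)) {
        stop("cohort ROI set does not match the model")
    }
    th <- thicknessMatrix(cohort)
    X <- .imputeEducation(covariateMatrix(cohort), cid, model@eduMedians)
    w <- matrix(NA_real_, nrow(th), ncol(th),
                dimnames = dimnames(th))
    for (id in unique(cid)) {
        rows <- which(cid == id)
        j <- match(id, model@centers$id)
        pred <- matrix(model@alpha[j, ], length(rows), ncol(th),
                       byrow = TRUE) +
            X[rows, , drop = FALSE] %*% model@beta[j, , ]
        w[rows, ] <- (th[rows, , drop = FALSE] - pred) /
            matrix(model@residSd[j, ], length(rows), ncol(th), byrow = TRUE)
    }
    .newWScoreExperiment(cohort, w)
}

#' @rdname harmonize
setMethod("harmonize", "SelfWModel", function(object, cohort, ...) {
    scoreSelfW(object, cohort)
})

#' @rdname modelCenters
setMethod("modelCenters", "SelfWModel", function(object) object@centers$id)

#' @rdname roiNames
setMethod("roiNames", "SelfWModel", function(x) x@roiNames)

setMethod("show", "SelfWModel", function(object) {
    cat(sprintf(
        "SelfWModel: %d center(s) x %d ROIs (robust per-center w-score)\n",
        nrow(object@centers), length(object@roiNames)))
})
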