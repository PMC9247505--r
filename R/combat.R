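#' @include cohort-class.R
NULL

# Conditional-posterior-mean recursion for the parametric EB batch estimates
# of one batch, vectorized over ROIs. gammaHat/delta2Hat are the batch sample
# moments of the standardized data; sumZ/sumZ2 are per-ROI sums over the
# batch's scans; (gbar, t2) the normal prior moments, (lambda, theta) the
# inverse-gamma prior parameters.
.combatEbFixedPoint <- function(gammaHat, delta2Hat, gbar, t2, lambda, theta,
                                sumZ, sumZ2, n, tol = 1e-6, maxit = 500L) {
    g <- gammaHat
    d2 <- delta2Hat
    for (it in seq_len(maxit)) {
        gNew <- (n * t2 * gammaHat + d2 * gbar) / (n * t2 + d2)
        sse <- sumZ2 - 2 * gNew * sumZ + n * gNew^2
        d2New <- (theta + 0.5 * sse) / (n / 2 + lambda - 1)
        delta <- max(abs(gNew - g), abs(d2New - d2))
        g <- gNew
        d2 <- d2New
        if (delta < tol) break
    }
    list(gammaStar = g, delta2Star = d2, iterations = it,
         converged = delta < tol)
}

#' Fit a ComBat location/scale harmonization model
#'
#' Fits the pooled covariate regression on the cognitively normal scans with
#' per-center additive offsets constrained to average out (weighted by center
#' size), standardizes residuals by the pooled SD, and shrinks each center's
#' additive (gamma) and multiplicative (delta^2) batch moments by parametric
#' empirical Bayes: a normal prior on gamma and an inverse-gamma prior on
#' delta^2, hyperparameters by method of moments across ROIs, solved by
#' fixed-point iteration of the conditional posterior means.
#'
#' The model is fitted on CN scans only and applied to all scans, matching
#' the comparator design of the harmonization study (the original ComBat
#' formulation fits on all scans).
#'
#' @param cohort A [CohortExperiment] with at least 2 centers and >= 2 CN
#'   scans per center.
#' @param tol,maxit Fixed-point iteration control.
#' @return A [ComBatModel].
#' @seealso [applyComBat()]
#' @export
fitComBat <- function(cohort, tol = 1e-6, maxit = 500L) {
    cn <- .cnSubset(cohort)
    eduMed <- .eduMedians(cohort)
    cn <- .dropNaEducation(cn, "fitComBat")
    idx <- .splitByCenter(cn)
    if (length(idx) < 2L) stop("ComBat requires >= 2 centers at fit time")
    if (any(lengths(idx) < 2L)) {
        stop("center(s) with < 2 CN scans: ",
             paste(names(idx)[lengths(idx) < 2L], collapse = ", "))
    }
    rois <- roiNames(cn)
    K <- length(rois)
    J <- length(idx)
    N <- ncol(cn)
    th <- thicknessMatrix(cn)
    X <- covariateMatrix(cn)
    batch <- factor(centerIds(cn), levels = names(idx))
    for (j in names(idx)) {
        v <- apply(th[idx[[j]], , drop = FALSE], 2L, stats::var)
        if (any(v <= 0)) {
            stop(sprintf("zero within-center variance: center '%s', ROI '%s'",
                         j, rois[which(v <= 0)[1L]]))
        }
    }
    # batch one-hot + covariates; per-ROI OLS in one multi-response solve
    design <- cbind(stats::model.matrix(~ 0 + batch), X)
    qrD <- qr(design)
    if (qrD$rank < ncol(design)) stop("rank-deficient ComBat design")
    B <- qr.coef(qrD, th)                       # (J + p) x K
    gRaw <- B[seq_len(J), , drop = FALSE]       # batch intercepts
    beta <- B[-seq_len(J), , drop = FALSE]
    nj <- lengths(idx)
    alpha <- as.numeric(crossprod(nj / N, gRaw)) # size-weighted grand mean
    fitted <- design %*% B
    pooledSd <- sqrt(colSums((th - fitted)^2) / N)
    stand <- (th - matrix(alpha, N, K, byrow = TRUE) - X %*% beta) /
        matrix(pooledSd, N, K, byrow = TRUE)

    gammaHat <- matrix(NA_real_, J, K, dimnames = list(names(idx), rois))
    delta2Hat <- gammaHat
    for (j in seq_len(J)) {
        Zj <- stand[idx[[j]], , drop = FALSE]
        gammaHat[j, ] <- colMeans(Zj)
        delta2Hat[j, ] <- apply(Zj, 2L, stats::var)
    }
    gammaStar <- gammaHat
    delta2Star <- delta2Hat
    hyper <- data.frame(id = names(idx), gamma_bar = NA_real_,
                        tau2 = NA_real_, lambda = NA_real_, theta = NA_real_,
                        stringsAsFactors = FALSE)
    if (K >= 2L) {
        for (j in seq_len(J)) {
            gbar <- mean(gammaHat[j, ])
            t2 <- stats::var(gammaHat[j, ])
            m <- mean(delta2Hat[j, ])
            s2 <- stats::var(delta2Hat[j, ])
            lambda <- (m^2 + 2 * s2) / s2
            theta <- (m^3 + m * s2) / s2
            Zj <- stand[idx[[j]], , drop = FALSE]
            fp <- .combatEbFixedPoint(
                gammaHat[j, ], delta2Hat[j, ], gbar, t2, lambda, theta,
                sumZ = colSums(Zj), sumZ2 = colSums(Zj^2), n = nrow(Zj),
                tol = tol, maxit = maxit)
            gammaStar[j, ] <- fp$gammaStar
            delta2Star[j, ] <- fp$delta2Star
            hyper[j, -1L] <- c(gbar, t2, lambda, theta)
        }
    } else {
        warning("single ROI: empirical-Bayes shrinkage unavailable, ",
                "using per-center sample moments")
    }
    methods::new("ComBatModel", roiNames = rois,
                 covariateNames = .COVARIATE_NAMES,
                 alpha = alpha, beta = beta, pooledSd = pooledSd,
                 gammaStar = gammaStar, deltaStar = sqrt(delta2Star),
                 hyper = hyper,
                 centers = data.frame(id = names(idx), n_cn = as.integer(nj),
                                      stringsAsFactors = FALSE),
                 eduMedians = eduMed, version = .MODEL_FORMAT_VERSION)
}

#' Apply a fitted ComBat model
#'
#' Harmonized thickness = pooledSd * (z - gamma*_j) / delta*_j + alpha +
#' X beta, with z the standardized residual of the scan; i.e. the covariate
#' effects are removed, the center's shrunken additive and multiplicative
#' batch effects are divided out on the standardized scale, and the
#' covariate effects restored. The output is thickness in mm, not a w-score.
#'
#' @param model A [ComBatModel].
#' @param cohort A [CohortExperiment] whose centers were all present at fit.
#' @return A [CohortExperiment] with harmonized thickness.
#' @export
applyComBat <- function(model, cohort) {
    cid <- centerIds(cohort)
    unknown <- setdiff(unique(cid), model@centers$id)
    if (length(unknown)) {
        stop("cannot harmonize scans from center(s) not fitted: ",
             paste(unknown, collapse = ", "))
    }
    if (!identical(roiNames(cohort), model@roiNames)) {
        stop("cohort ROI set does not match the model")
    }
    th <- thicknessMatrix(cohort)
    X <- .imputeEducation(covariateMatrix(cohort), cid, model@eduMedians)
    n <- nrow(th)
    K <- ncol(th)
    covPart <- matrix(model@alpha, n, K, byrow = TRUE) + X %*% model@beta
    z <- (th - covPart) / matrix(model@pooledSd, n, K, byrow = TRUE)
    j <- match(cid, model@centers$id)
    zAdj <- (z - model@gammaStar[j, , drop = FALSE]) /
        model@deltaStar[j, , drop = FALSE]
    out <- zAdj * matrix(model@pooledSd, n, K, byrow = TRUE) + covPart
    cd <- SummarizedExperiment::colData(cohort)
    CohortExperiment(out, subject_id = cd$subject_id,
                     center_id = cd$center_id,
                     diagnosis = as.character(cd$diagnosis),
                     age = cd$age, sex = cd$sex, education = cd$education,
                     icv = cd$icv)
}

#' @rdname harmonize
setMethod("harmonize", "ComBatModel", function(object, cohort, ...) {
    applyComBat(object, cohort)
})

#' @rdname modelCenters
setMethod("modelCenters", "ComBatModel", function(object) object@centers$id)

#' @rdname roiNames
setMethod("roiNames", "ComBatModel", function(x) x@roiNames)

setMethod("show", "ComBatModel", function(object) {
    cat(sprintf(
        "ComBatModel: %d center(s) x %d ROIs (EB location/scale)\n",
        nrow(object@centers), length(object@roiNames)))
})
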