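#' @include cohort-class.R
NULL

# ---- compound-symmetry sufficient statistics -------------------------------
# With a single random intercept per center, Sigma_j = sigma2 I + d 11' and
#   Sigma_j^{-1} = (I - w_j/ d * ... ) reduces to scalar weights
#   w_j = d / (sigma2 + n_j d), so every GLS quantity is a function of the
# per-center moments X'X, X'y, column sums and y'y only. All fits therefore
# cost O(#centers p^2) per objective evaluation, independent of n.

.designMatrix <- function(cohort, eduMedians = NULL) {
    X <- covariateMatrix(cohort)
    if (!is.null(eduMedians)) {
        X <- .imputeEducation(X, centerIds(cohort), eduMedians)
    }
    cbind(`(Intercept)` = 1, X)
}

.checkFullRank <- function(X1) {
    qrX <- qr(X1, LAPACK = TRUE)
    if (qrX$rank < ncol(X1)) {
        bad <- colnames(X1)[qrX$pivot[(qrX$rank + 1L):ncol(X1)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    invisible(TRUE)
}

.lmeSuffStats <- function(X1, Y, centers) {
    idx <- split(seq_len(nrow(X1)), factor(centers, levels = unique(centers)))
    J <- length(idx)
    q <- ncol(X1)
    S1x <- matrix(0, q, J)
    S1y <- matrix(0, J, ncol(Y))
    for (j in seq_len(J)) {
        S1x[, j] <- colSums(X1[idx[[j]], , drop = FALSE])
        S1y[j, ] <- colSums(Y[idx[[j]], , drop = FALSE])
    }
    list(ids = names(idx), n = lengths(idx), N = nrow(X1),
         SxxTot = crossprod(X1), SxyTot = crossprod(X1, Y),
         SyyTot = colSums(Y^2), S1x = S1x, S1y = S1y, idx = idx)
}

# Core ReML quantities for one ROI at (d, sigma2) from sufficient stats.
# The compound-symmetry inverse contributes only rank-1 corrections per
# center, so A = X'Sigma^{-1}X etc. need the totals plus per-center column
# sums. Returns A, rhs c = X'Sigma^{-1}y, quad = y'Sigma^{-1}y, and
# sum_j log|Sigma_j|.
.remlCore <- function(d, sigma2, ss, k) {
    wj <- d / (sigma2 + ss$n * d)
    S1xw <- sweep(ss$S1x, 2L, wj, `*`)
    list(A = (ss$SxxTot - tcrossprod(S1xw, ss$S1x)) / sigma2,
         cc = (ss$SxyTot[, k] - as.numeric(S1xw %*% ss$S1y[, k])) / sigma2,
         quad = (ss$SyyTot[k] - sum(wj * ss$S1y[, k]^2)) / sigma2,
         logdet = (ss$N - length(ss$n)) * log(sigma2) +
             sum(log(sigma2 + ss$n * d)))
}

# Scale-robust solve of A beta = cc with log-determinant of A; columns are
# equilibrated first because raw-unit covariates (ICV ~ 1e6 mm^3) make A
# badly conditioned.
.solveInfo <- function(A, cc) {
    sc <- sqrt(diag(A))
    if (any(!is.finite(sc) | sc <= 0)) stop("degenerate information matrix")
    As <- A / tcrossprod(sc)
    R <- tryCatch(chol(As), error = function(e) {
        stop("rank-deficient design; collinear covariates")
    })
    betaS <- backsolve(R, backsolve(R, cc / sc, transpose = TRUE))
    list(beta = betaS / sc,
         logdetA = 2 * sum(log(diag(R))) + 2 * sum(log(sc)),
         Ainv = {
             Rs <- backsolve(R, diag(length(sc)))
             tcrossprod(Rs) / tcrossprod(sc)
         })
}

.remlValue <- function(d, sigma2, ss, k) {
    core <- .remlCore(d, sigma2, ss, k)
    sol <- .solveInfo(core$A, core$cc)
    rss <- core$quad - sum(core$cc * sol$beta)
    n <- sum(ss$n)
    q <- nrow(ss$S1x)
    -0.5 * core$logdet - 0.5 * sol$logdetA - 0.5 * rss -
        0.5 * (n - q) * log(2 * pi)
}

#' Restricted log-likelihood of the random-intercept model
#'
#' Evaluates the ReML criterion for one ROI at given variance components,
#' with the fixed effects profiled out by generalized least squares:
#' -1/2 sum_j log|Sigma_j| - 1/2 log|sum_j X_j' Sigma_j^{-1} X_j|
#' - 1/2 r' Sigma^{-1} r - (n-q)/2 log(2 pi), where
#' Sigma_j = sigma2 I + d 11' for center j. The compound-symmetry structure
#' is exploited in closed form; no n x n matrix is built.
#'
#' @param d Random-intercept variance (mm^2), >= 0.
#' @param sigma2 Residual variance (mm^2), > 0.
#' @param cohort A [CohortExperiment]; CN scans are used.
#' @param roi ROI name or index.
#' @param cnOnly Restrict to CN scans (default TRUE, the fitting reference).
#' @return The restricted log-likelihood (scalar).
#' @export
remlObjective <- function(d, sigma2, cohort, roi = 1L, cnOnly = TRUE) {
    if (sigma2 <= 0) stop("sigma2 must be > 0")
    if (d < 0) stop("d must be >= 0")
    dat <- if (cnOnly) .cnSubset(cohort) else cohort
    dat <- .dropNaEducation(dat, "remlObjective")
    X1 <- .designMatrix(dat)
    Y <- thicknessMatrix(dat)
    k <- if (is.character(roi)) match(roi, colnames(Y)) else as.integer(roi)
    ss <- .lmeSuffStats(X1, Y, centerIds(dat))
    unname(.remlValue(d, sigma2, ss, k))
}

#' Generalized least-squares fixed effects at given variance components
#'
#' beta = (sum_j X_j' Sigma_j^{-1} X_j)^{-1} sum_j X_j' Sigma_j^{-1} y_j
#' with the compound-symmetry closed-form inverse per center, solved (not
#' inverted) after column equilibration so raw-unit ICV covariates are
#' handled stably.
#'
#' @inheritParams remlObjective
#' @return Named numeric: `(Intercept)`, `age`, `sex`, `education`, `icv`.
#' @export
betaGLS <- function(d, sigma2, cohort, roi = 1L, cnOnly = TRUE) {
    if (sigma2 <= 0) stop("sigma2 must be > 0")
    if (d < 0) stop("d must be >= 0")
    dat <- if (cnOnly) .cnSubset(cohort) else cohort
    dat <- .dropNaEducation(dat, "betaGLS")
    X1 <- .designMatrix(dat)
    .checkFullRank(X1)
    Y <- thicknessMatrix(dat)
    k <- if (is.character(roi)) match(roi, colnames(Y)) else as.integer(roi)
    ss <- .lmeSuffStats(X1, Y, centerIds(dat))
    core <- .remlCore(d, sigma2, ss, k)
    sol <- .solveInfo(core$A, core$cc)
    stats::setNames(sol$beta, colnames(X1))
}

# Multi-start quasi-Newton maximization of the ReML criterion for ROI k on
# (log d, log sigma2), with an explicit d -> 0 boundary fallback.
.fitOneRoi <- function(ss, k, nStarts = 5L) {
    n <- sum(ss$n)
    # pooled OLS residual variance seeds the variance grid
    core0 <- .remlCore(0, 1, ss, k)  # sigma2=1, d=0 => A = X'X, cc = X'y
    sol0 <- .solveInfo(core0$A, core0$cc)
    v <- max((core0$quad - sum(core0$cc * sol0$beta)) / (n - length(sol0$beta)),
             1e-10)
    iccGrid <- c(1e-3, 0.05, 0.2, 0.5, 0.8)[seq_len(nStarts)]
    negobj <- function(par) {
        if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
        val <- tryCatch(
            suppressWarnings(.remlValue(exp(par[1L]), exp(par[2L]), ss, k)),
            error = function(e) NA_real_)
        if (!is.finite(val)) 1e10 else -val
    }
    best <- NULL
    trace <- data.frame(start_icc = iccGrid, value = NA_real_,
                        converged = FALSE)
    lower <- log(c(1e-9 * v, 1e-6 * v))
    upper <- log(c(1e4 * v, 1e4 * v))
    for (i in seq_along(iccGrid)) {
        par0 <- pmin(pmax(log(c(max(iccGrid[i] * v, 1e-8),
                                (1 - iccGrid[i]) * v)), lower), upper)
        opt <- tryCatch(
            stats::optim(par0, negobj, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(factr = 1e7, maxit = 100L)),
            error = function(e) NULL)
        if (is.null(opt)) next
        trace$value[i] <- -opt$value
        trace$converged[i] <- opt$convergence == 0L
        if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) {
        stop("ReML optimization failed for ROI index ", k,
             " after all multi-starts")
    }
    d <- exp(best$par[1L])
    sigma2 <- exp(best$par[2L])
    value <- -best$value
    # boundary fallback: profile sigma2 at d = 0
    prof0 <- stats::optimize(function(ls2) -.remlValue(0, exp(ls2), ss, k),
                             interval = log(v) + c(-8, 8), tol = 1e-12)
    boundary <- FALSE
    if (-prof0$objective >= value) {
        d <- 0
        sigma2 <- exp(prof0$minimum)
        value <- -prof0$objective
        boundary <- TRUE
    }
    core <- .remlCore(d, sigma2, ss, k)
    sol <- .solveInfo(core$A, core$cc)
    wj <- d / (sigma2 + ss$n * d)
    b <- wj * (ss$S1y[, k] - as.numeric(crossprod(ss$S1x, sol$beta)))
    list(d = d, sigma2 = sigma2, value = value, beta = sol$beta,
         betaCov = sol$Ainv, b = b,
         converged = any(trace$converged) || boundary, trace = trace)
}

#' Fit the linear mixed-effects w-score model
#'
#' One independent random-intercept model per ROI, fitted on the cognitively
#' normal scans of all centers: thickness ~ age + sex + education + ICV as
#' fixed effects, center as a random intercept (exchangeable variance `d`),
#' residual variance `sigma2`. Variance components maximize the restricted
#' likelihood (quasi-Newton on the log scale, multi-start, with a d = 0
#' boundary fallback); fixed effects come from the closed-form GLS step at
#' the optimum; per-center intercepts are BLUPs
#' b_j = d 1' Sigma_j^{-1} (y_j - X_j beta); the w-score scale `s` is the
#' SD of the pooled CN conditional residuals.
#'
#' @param cohort A [CohortExperiment] with >= 2 centers.
#' @param nStarts Number of optimizer multi-starts (variance-ratio grid).
#' @param allowSingleCenter Permit a one-center fit (the random-intercept
#'   variance is then weakly identified and typically estimated at 0); used
#'   by the scalability protocol, off by default.
#' @return An [LMEModel].
#' @seealso [scoreLME()], [addCenter()], [remlObjective()], [betaGLS()]
#' @export
fitLME <- function(cohort, nStarts = 5L, allowSingleCenter = FALSE) {
    cn <- .cnSubset(cohort)
    eduMed <- .eduMedians(cohort)
    cn <- .dropNaEducation(cn, "fitLME")
    ids <- unique(centerIds(cn))
    if (length(ids) < 2L && !allowSingleCenter) {
        stop("LME fit requires >= 2 centers")
    }
    X1 <- .designMatrix(cn)
    if (ncol(cn) <= ncol(X1) - 1L + 3L) {
        stop("too few CN scans for a stable fit")
    }
    .checkFullRank(X1)
    Y <- thicknessMatrix(cn)
    rois <- colnames(Y)
    K <- length(rois)
    ss <- .lmeSuffStats(X1, Y, centerIds(cn))
    q <- ncol(X1)
    alpha <- numeric(K)
    beta <- matrix(NA_real_, q - 1L, K,
                   dimnames = list(.COVARIATE_NAMES, rois))
    d <- numeric(K)
    sigma2 <- numeric(K)
    b <- matrix(NA_real_, length(ss$ids), K, dimnames = list(ss$ids, rois))
    betaCov <- array(NA_real_, c(q, q, K),
                     dimnames = list(colnames(X1), colnames(X1), rois))
    s <- numeric(K)
    conv <- logical(K)
    value <- numeric(K)
    centerOf <- match(centerIds(cn), ss$ids)
    for (k in seq_len(K)) {
        fit <- .fitOneRoi(ss, k, nStarts = nStarts)
        alpha[k] <- fit$beta[1L]
        beta[, k] <- fit$beta[-1L]
        d[k] <- fit$d
        sigma2[k] <- fit$sigma2
        b[, k] <- fit$b
        betaCov[, , k] <- fit$betaCov
        value[k] <- fit$value
        conv[k] <- fit$converged
        resid <- Y[, k] - as.numeric(X1 %*% fit$beta) - fit$b[centerOf]
        s[k] <- stats::sd(resid)
    }
    if (!all(conv)) {
        stop("ReML optimizer failed to converge for ROI(s): ",
             paste(utils::head(rois[!conv], 5L), collapse = ", "))
    }
    names(alpha) <- rois
    names(d) <- rois
    names(sigma2) <- rois
    names(s) <- rois
    methods::new("LMEModel", roiNames = rois,
                 covariateNames = .COVARIATE_NAMES,
                 alpha = alpha, beta = beta, d = d, sigma2 = sigma2,
                 b = b, s = s, betaCov = betaCov,
                 centers = data.frame(id = ss$ids,
                                      n_cn = as.integer(ss$n),
                                      added = FALSE,
                                      stringsAsFactors = FALSE),
                 eduMedians = eduMed,
                 diagnostics = list(converged = conv, reml = value),
                 version = .MODEL_FORMAT_VERSION)
}

#' Score a cohort with a fitted LME model
#'
#' w = (y - yhat) / s per ROI, with yhat the conditional mean
#' alpha + X beta + b_j for scans from centers known to the model. For
#' centers the model has never seen, `policy` selects the behaviour:
#' `"marginal"` (default) scores against the marginal mean alpha + X beta
#' (b = 0) — this is what allows scoring a center with no normative
#' reference of its own; `"blup-from-data"` predicts the center intercept
#' from the scored scans themselves (their CN scans when present) with the
#' frozen variance components; `"strict"` refuses.
#'
#' @param model An [LMEModel].
#' @param cohort A [CohortExperiment].
#' @param policy Unseen-center policy.
#' @return A [WScoreExperiment].
#' @export
scoreLME <- function(model, cohort,
                     policy = c("marginal", "strict", "blup-from-data")) {
    policy <- match.arg(policy)
    if (!identical(roiNames(cohort), model@roiNames)) {
        stop("cohort ROI set does not match the model")
    }
    cid <- centerIds(cohort)
    unknown <- setdiff(unique(cid), model@centers$id)
    if (length(unknown) && policy == "strict") {
        stop("unregistered center(s): ", paste(unknown, collapse = ", "))
    }
    th <- thicknessMatrix(cohort)
    X1 <- .designMatrix(cohort, model@eduMedians)
    n <- nrow(th)
    K <- ncol(th)
    fixedPred <- matrix(model@alpha, n, K, byrow = TRUE) +
        X1[, -1L, drop = FALSE] %*% model@beta
    bmat <- matrix(0, n, K)
    j <- match(cid, model@centers$id)
    seen <- !is.na(j)
    if (any(seen)) bmat[seen, ] <- model@b[j[seen], , drop = FALSE]
    if (length(unknown) && policy == "blup-from-data") {
        for (id in unknown) {
            rows <- which(cid == id)
            ref <- rows[diagnoses(cohort)[rows] == "CN"]
            if (!length(ref)) {
                warning("center '", id, "': no CN scans, predicting its ",
                        "intercept from all of its scans")
                ref <- rows
            }
            resid <- th[ref, , drop = FALSE] - fixedPred[ref, , drop = FALSE]
            nr <- length(ref)
            shrink <- nr * model@d / (model@sigma2 + nr * model@d)
            bNew <- shrink * colMeans(resid)
            bmat[rows, ] <- matrix(bNew, length(rows), K, byrow = TRUE)
        }
    }
    w <- (th - fixedPred - bmat) /
        matrix(model@s, n, K, byrow = TRUE)
    .newWScoreExperiment(cohort, w)
}

#' @rdname harmonize
setMethod("harmonize", "LMEModel", function(object, cohort,
                                            policy = "marginal", ...) {
    scoreLME(object, cohort, policy = policy)
})

#' Register a new center without refitting
#'
#' Fixed effects and variance components are frozen; the new center's
#' intercept is its BLUP under the existing model,
#' b = n d / (sigma2 + n d) * mean(y - alpha - X beta), computed from the
#' center's CN scans. Existing centers' parameters — and therefore their
#' w-scores — are untouched. With fewer than 2 CN scans the center is
#' registered with b = 0 (marginal scoring) and a warning.
#'
#' @param object A fitted [LMEModel].
#' @param newData A [CohortExperiment] holding one previously unregistered
#'   center.
#' @param ... Unused.
#' @return The updated [LMEModel].
#' @export
setMethod("addCenter", "LMEModel", function(object, newData, ...) {
    ids <- unique(centerIds(newData))
    if (length(ids) != 1L) {
        stop("newData must contain exactly one center, found: ",
             paste(ids, collapse = ", "))
    }
    if (ids %in% object@centers$id) {
        stop("center '", ids, "' is already registered")
    }
    if (!identical(roiNames(newData), object@roiNames)) {
        stop("ROI set does not match the model")
    }
    cn <- .cnSubset(newData)
    cn <- .dropNaEducation(cn, "addCenter")
    K <- length(object@roiNames)
    if (ncol(cn) < 2L) {
        warning("center '", ids, "' has < 2 CN scans; registered with b = 0 ",
                "(marginal scoring)")
        bNew <- numeric(K)
        nUsed <- ncol(cn)
    } else {
        th <- thicknessMatrix(cn)
        X1 <- .designMatrix(cn, object@eduMedians)
        fixedPred <- matrix(object@alpha, nrow(th), K, byrow = TRUE) +
            X1[, -1L, drop = FALSE] %*% object@beta
        nUsed <- nrow(th)
        shrink <- nUsed * object@d / (object@sigma2 + nUsed * object@d)
        bNew <- shrink * colMeans(th - fixedPred)
        edu <- X1[, "education"]
        object@eduMedians[ids] <- stats::median(edu)
    }
    object@b <- rbind(object@b, matrix(bNew, 1L, K,
                                       dimnames = list(ids, NULL)))
    object@centers <- rbind(object@centers,
                            data.frame(id = ids, n_cn = as.integer(nUsed),
                                       added = TRUE))
    methods::validObject(object)
    object
})

#' @rdname modelCenters
setMethod("modelCenters", "LMEModel", function(object) object@centers$id)

#' @rdname roiNames
setMethod("roiNames", "LMEModel", function(x) x@roiNames)

setMethod("show", "LMEModel", function(object) {
    cat(sprintf(
        "LMEModel: %d ROIs, %d center(s) (%d added post hoc)\n",
        length(object@roiNames), nrow(object@centers),
        sum(object@centers$added)))
    icc <- object@d / (object@d + object@sigma2)
    cat(sprintf("  intraclass correlation (center): median %.3f [%.3f, %.3f]\n",
                stats::median(icc), min(icc), max(icc)))
})
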