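#' @include AllClasses.R AllGenerics.R
NULL

.mat2json <- function(m) {
    list(dim = dim(m), dimnames = dimnames(m), data = as.numeric(m))
}

.json2mat <- function(x) {
    m <- matrix(as.numeric(x$data), x$dim[[1]], x$dim[[2]])
    dn <- x$dimnames
    if (!is.null(dn)) {
        # jsonlite simplifies equal-length name vectors to a matrix
        if (is.matrix(dn)) dn <- lapply(seq_len(nrow(dn)), function(i) dn[i, ])
        dimnames(m) <- lapply(dn, function(d) {
            if (length(d)) as.character(d) else NULL
        })
    }
    m
}

.writeModelJson <- function(payload, path) {
    # I(17) emits 17 significant digits: doubles round-trip exactly
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
    invisible(path)
}

.readModelJson <- function(path, expectMethod = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- tryCatch(
        jsonlite::read_json(path, simplifyVector = TRUE),
        error = function(e) stop("corrupted model file '", path, "': ",
                                 conditionMessage(e)))
    if (is.null(obj$format_version) || is.null(obj$method)) {
        stop("corrupted model file '", path, "': missing header fields")
    }
    if (obj$format_version > .MODEL_FORMAT_VERSION) {
        stop("model file format version ", obj$format_version,
             " is newer than supported version ", .MODEL_FORMAT_VERSION)
    }
    obj
}

#' @rdname saveModel
setMethod("saveModel", "SelfWModel", function(object, path) {
    betaList <- lapply(seq_len(nrow(object@centers)), function(j) {
        .mat2json(object@beta[j, , ])
    })
    names(betaList) <- object@centers$id
    .writeModelJson(list(
        format_version = object@version, method = "selfw",
        roi_names = object@roiNames, covariate_names = object@covariateNames,
        parameters = list(alpha = .mat2json(object@alpha), beta = betaList,
                          resid_sd = .mat2json(object@residSd)),
        fit_metadata = list(centers = object@centers,
                            edu_medians = as.list(object@eduMedians))), path)
})

#' @rdname saveModel
setMethod("saveModel", "ComBatModel", function(object, path) {
    .writeModelJson(list(
        format_version = object@version, method = "combat",
        roi_names = object@roiNames, covariate_names = object@covariateNames,
        parameters = list(alpha = object@alpha, beta = .mat2json(object@beta),
                          pooled_sd = object@pooledSd,
                          gamma_star = .mat2json(object@gammaStar),
                          delta_star = .mat2json(object@deltaStar),
                          hyper = object@hyper),
        fit_metadata = list(centers = object@centers,
                            edu_medians = as.list(object@eduMedians))), path)
})

#' @rdname saveModel
setMethod("saveModel", "LMEModel", function(object, path) {
    covList <- list(dim = dim(object@betaCov),
                    data = as.numeric(object@betaCov))
    .writeModelJson(list(
        format_version = object@version, method = "lme",
        roi_names = object@roiNames, covariate_names = object@covariateNames,
        parameters = list(alpha = object@alpha, beta = .mat2json(object@beta),
                          d = object@d, sigma2 = object@sigma2,
                          b = .mat2json(object@b), s = object@s,
                          beta_cov = covList),
        fit_metadata = list(centers = object@centers,
                            edu_medians = as.list(object@eduMedians),
                            diagnostics = object@diagnostics)), path)
})

#' Load a serialized harmonization model
#'
#' Restores a model written by [saveModel()]. Values are stored at full
#' double precision, so a reloaded model scores bit-for-bit identically to
#' the in-memory model it was saved from.
#'
#' @param path JSON model file.
#' @return A [SelfWModel], [ComBatModel] or [LMEModel], per the file's
#'   `method` field.
#' @export
loadModel <- function(path) {
    obj <- .readModelJson(path)
    rois <- as.character(obj$roi_names)
    covs <- as.character(obj$covariate_names)
    centers <- as.data.frame(obj$fit_metadata$centers,
                             stringsAsFactors = FALSE)
    eduMed <- unlist(obj$fit_metadata$edu_medians)
    pp <- obj$parameters
    switch(obj$method,
        selfw = {
            J <- nrow(centers)
            beta <- array(NA_real_, c(J, length(covs), length(rois)),
                          dimnames = list(centers$id, covs, rois))
            for (j in seq_len(J)) {
                beta[j, , ] <- .json2mat(pp$beta[[centers$id[j]]])
            }
            methods::new("SelfWModel", roiNames = rois,
                         covariateNames = covs, alpha = .json2mat(pp$alpha),
                         beta = beta, residSd = .json2mat(pp$resid_sd),
                         centers = centers, eduMedians = eduMed,
                         version = as.integer(obj$format_version))
        },
        combat = {
            methods::new("ComBatModel", roiNames = rois,
                         covariateNames = covs,
                         alpha = as.numeric(pp$alpha),
                         beta = .json2mat(pp$beta),
                         pooledSd = as.numeric(pp$pooled_sd),
                         gammaStar = .json2mat(pp$gamma_star),
                         deltaStar = .json2mat(pp$delta_star),
                         hyper = as.data.frame(pp$hyper,
                                               stringsAsFactors = FALSE),
                         centers = centers, eduMedians = eduMed,
                         version = as.integer(obj$format_version))
        },
        lme = {
            q <- length(covs) + 1L
            betaCov <- array(as.numeric(pp$beta_cov$data),
                             as.integer(pp$beta_cov$dim))
            dimnames(betaCov) <- list(c("(Intercept)", covs),
                                      c("(Intercept)", covs), rois)
            dg <- obj$fit_metadata$diagnostics
            methods::new("LMEModel", roiNames = rois, covariateNames = covs,
                         alpha = stats::setNames(as.numeric(pp$alpha), rois),
                         beta = .json2mat(pp$beta),
                         d = stats::setNames(as.numeric(pp$d), rois),
                         sigma2 = stats::setNames(as.numeric(pp$sigma2), rois),
                         b = .json2mat(pp$b),
                         s = stats::setNames(as.numeric(pp$s), rois),
                         betaCov = betaCov, centers = centers,
                         eduMedians = eduMed,
                         diagnostics = if (is.null(dg)) list() else
                             as.list(dg),
                         version = as.integer(obj$format_version))
        },
        stop("unknown model method: ", obj$method))
}
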