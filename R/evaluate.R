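#' @include cohort-class.R utils.R lme.R
NULL

#' Repeated PCA-LDA classification result
#'
#' Summary of the repeated undersampled in-sample PCA-LDA probe. Sensitivity
#' and specificity are defined with the patient group as the positive class
#' (for center prediction, the second center).
#'
#' @slot accuracy,sensitivity,specificity Mean proportions over repeats.
#' @slot perRepeat data.frame with one row per repeat.
#' @slot nPerClass Class size after undersampling.
#' @slot positiveClass Label treated as positive.
#' @slot seed Seed that reproduces the result.
#' @export
setClass("ClassificationResult", representation(
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    perRepeat = "data.frame", nPerClass = "integer",
    positiveClass = "character", seed = "integer"))

setMethod("show", "ClassificationResult", function(object) {
    cat(sprintf(
        "ClassificationResult (%d repeats, %d/class): acc %.3f sen %.3f spe %.3f\n",
        nrow(object@perRepeat), object@nPerClass, object@accuracy,
        object@sensitivity, object@specificity))
})

.featureBlock <- function(features) {
    if (methods::is(features, "WScoreExperiment")) return(wscoreMatrix(features))
    if (methods::is(features, "CohortExperiment")) return(thicknessMatrix(features))
    as.matrix(features)
}

#' Repeated undersampled PCA-LDA classification
#'
#' The residual-signal probe of the harmonization study: per repeat, the
#' majority class is undersampled (without replacement) to the minority
#' size, features are centered on the undersampled set, projected onto
#' principal components, classified by linear discriminant analysis, and —
#' deliberately — evaluated on the same training set: if even the in-sample
#' optimal linear discriminator cannot separate the classes, no residual
#' signal is present. A stratified held-out mode is available for general
#' use via `heldOut`.
#'
#' The number of retained components is
#' `min(maxComponents, #components reaching varExplained, n - 2)`; the
#' small fixed cap keeps the in-sample optimism of this deliberately
#' optimistic protocol bounded.
#'
#' @param features Numeric matrix (scans x features), [CohortExperiment] or
#'   [WScoreExperiment].
#' @param labels Two-level factor (or coercible), one label per scan.
#' @param nRepeats Number of undersampling repeats (default 30).
#' @param seed Integer seed; fully determines the result.
#' @param maxComponents Cap on retained principal components.
#' @param varExplained Cumulative variance threshold.
#' @param heldOut If TRUE, evaluate on a stratified 30% held-out split
#'   instead of the training set.
#' @return A [ClassificationResult].
#' @export
pcaLdaClassify <- function(features, labels, nRepeats = 30L, seed = 1L,
                           maxComponents = 10L, varExplained = 0.95,
                           heldOut = FALSE) {
    feat <- .featureBlock(features)
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    if (nRepeats < 1L) stop("nRepeats must be >= 1")
    counts <- table(labels)
    if (min(counts) < 3L) {
        stop("minority class has ", min(counts), " scans (< 3)")
    }
    pos <- if ("CN" %in% levels(labels)) {
        setdiff(levels(labels), "CN")
    } else {
        levels(labels)[2L]
    }
    nMin <- as.integer(min(counts))
    res <- .withSeed(seed, {
        out <- matrix(NA_real_, nRepeats, 3L)
        for (r in seq_len(nRepeats)) {
            take <- unlist(lapply(levels(labels), function(l) {
                i <- which(labels == l)
                if (length(i) > nMin) sample(i, nMin) else i
            }))
            stopifnot(!anyDuplicated(take))
            if (heldOut) {
                test <- unlist(lapply(levels(labels), function(l) {
                    i <- take[labels[take] == l]
                    sample(i, max(1L, round(0.3 * length(i))))
                }))
                train <- setdiff(take, test)
            } else {
                train <- take
                test <- take
            }
            ctr <- colMeans(feat[train, , drop = FALSE])
            Xtr <- sweep(feat[train, , drop = FALSE], 2L, ctr)
            pc <- stats::prcomp(Xtr, center = FALSE)
            ev <- pc$sdev^2
            keep <- ev > max(ev) * 1e-9
            cum <- cumsum(ev[keep]) / sum(ev[keep])
            npc <- min(maxComponents, which(cum >= varExplained)[1L],
                       sum(keep), length(train) - 2L)
            P <- pc$rotation[, seq_len(npc), drop = FALSE]
            fit <- suppressWarnings(
                MASS::lda(Xtr %*% P, grouping = labels[train]))
            Xte <- sweep(feat[test, , drop = FALSE], 2L, ctr) %*% P
            pred <- stats::predict(fit, Xte)$class
            truth <- labels[test]
            out[r, 1L] <- mean(pred == truth)
            out[r, 2L] <- mean(pred[truth == pos] == pos)
            out[r, 3L] <- mean(pred[truth != pos] != pos)
        }
        out
    })
    per <- data.frame(repeat_id = seq_len(nRepeats), accuracy = res[, 1L],
                      sensitivity = res[, 2L], specificity = res[, 3L])
    methods::new("ClassificationResult",
                 accuracy = mean(per$accuracy),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 perRepeat = per, nPerClass = nMin,
                 positiveClass = pos, seed = as.integer(seed))
}

#' Pairwise center-prediction experiment
#'
#' For every unordered pair of centers, predicts which center a scan came
#' from with [pcaLdaClassify()] (CN scans only by default). A grand mean
#' near 0.5 indicates the center effect has been removed from the features;
#' raw multicenter thickness typically classifies far above chance.
#'
#' @param features Feature container or matrix (scans x ROIs).
#' @param centers Center labels (taken from the container when omitted).
#' @param diagnosis Diagnosis labels (idem).
#' @param cnOnly Use CN scans only (default TRUE).
#' @param nRepeats,seed Passed to the classifier; each pair gets an
#'   independent substream of `seed`.
#' @param minPerCenter Centers contributing fewer scans are skipped with a
#'   warning.
#' @return List with `accuracy` (J x J symmetric matrix, NA diagonal),
#'   `grandMean` (mean over computed pairs), and `pairs` (data.frame).
#' @export
centerPrediction <- function(features, centers = NULL, diagnosis = NULL,
                             cnOnly = TRUE, nRepeats = 30L, seed = 1L,
                             minPerCenter = 3L) {
    if (is.null(centers)) centers <- centerIds(features)
    if (is.null(diagnosis) && methods::is(features, "SummarizedExperiment")) {
        diagnosis <- diagnoses(features)
    }
    feat <- .featureBlock(features)
    keep <- rep(TRUE, nrow(feat))
    if (cnOnly) {
        if (is.null(diagnosis)) stop("cnOnly = TRUE requires diagnosis labels")
        keep <- as.character(diagnosis) == "CN"
    }
    feat <- feat[keep, , drop = FALSE]
    centers <- as.character(centers)[keep]
    ids <- unique(centers)
    if (length(ids) < 2L) stop("need >= 2 centers")
    acc <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
    rows <- list()
    for (a in seq_along(ids)) {
        for (b in seq_along(ids)) {
            if (b <= a) next
            ra <- which(centers == ids[a])
            rb <- which(centers == ids[b])
            if (length(ra) < minPerCenter || length(rb) < minPerCenter) {
                warning(sprintf("skipping pair (%s, %s): too few scans",
                                ids[a], ids[b]))
                next
            }
            cl <- pcaLdaClassify(
                feat[c(ra, rb), , drop = FALSE],
                factor(rep(c(ids[a], ids[b]), c(length(ra), length(rb))),
                       levels = c(ids[a], ids[b])),
                nRepeats = nRepeats,
                seed = .streamSeed(seed, "pair", ids[a], ids[b]))
            acc[a, b] <- acc[b, a] <- cl@accuracy
            rows[[length(rows) + 1L]] <- data.frame(
                center_a = ids[a], center_b = ids[b],
                accuracy = cl@accuracy, sd = stats::sd(cl@perRepeat$accuracy))
        }
    }
    pairs <- do.call(rbind, rows)
    list(accuracy = acc,
         grandMean = if (is.null(pairs)) NA_real_ else mean(pairs$accuracy),
         pairs = pairs)
}

#' Per-center and merged disease-classification experiment
#'
#' CN-vs-patient PCA-LDA classification per center, plus a merged variant
#' pooling every center that carries AD patients (PD-only centers are
#' excluded from the merge) — the probe for whether harmonization preserves
#' the disease effect while removing the center effect.
#'
#' @param features Feature container or matrix.
#' @param diagnosis,centers Labels (taken from the container when omitted).
#' @param nRepeats,seed Classifier control.
#' @return List with `perCenter` (data.frame of acc/sen/spe), `merged`
#'   (a [ClassificationResult] or NULL), and `results` (per-center
#'   [ClassificationResult] objects).
#' @export
diseaseClassification <- function(features, diagnosis = NULL, centers = NULL,
                                  nRepeats = 30L, seed = 1L) {
    if (is.null(centers)) centers <- centerIds(features)
    if (is.null(diagnosis)) diagnosis <- diagnoses(features)
    feat <- .featureBlock(features)
    centers <- as.character(centers)
    dx <- as.character(diagnosis)
    ids <- unique(centers)
    results <- list()
    rows <- list()
    for (id in ids) {
        sel <- centers == id
        isCn <- dx[sel] == "CN"
        isPt <- dx[sel] %in% c("AD", "PD", "OTHER")
        if (sum(isCn) < 3L || sum(isPt) < 3L) {
            warning("skipping center '", id, "': needs >= 3 CN and >= 3 patients")
            next
        }
        sub <- which(sel)[isCn | isPt]
        lab <- factor(ifelse(dx[sub] == "CN", "CN", "patient"),
                      levels = c("CN", "patient"))
        cl <- pcaLdaClassify(feat[sub, , drop = FALSE], lab,
                             nRepeats = nRepeats,
                             seed = .streamSeed(seed, "disease", id))
        results[[id]] <- cl
        rows[[length(rows) + 1L]] <- data.frame(
            center = id, accuracy = cl@accuracy,
            sensitivity = cl@sensitivity, specificity = cl@specificity)
    }
    adCenters <- unique(centers[dx == "AD"])
    merged <- NULL
    if (length(adCenters)) {
        sub <- which(centers %in% adCenters & dx %in% c("CN", "AD"))
        if (sum(dx[sub] == "AD") >= 3L && sum(dx[sub] == "CN") >= 3L) {
            lab <- factor(ifelse(dx[sub] == "CN", "CN", "patient"),
                          levels = c("CN", "patient"))
            merged <- pcaLdaClassify(feat[sub, , drop = FALSE], lab,
                                     nRepeats = nRepeats,
                                     seed = .streamSeed(seed, "merged"))
        }
    }
    list(perCenter = do.call(rbind, rows), merged = merged,
         results = results)
}

#' Paired intrasubject comparison of raw and harmonized scales
#'
#' Every subject must have exactly one scan in each of two centers. Per
#' subject and center the whole-brain mean is computed on two comparable
#' scales: raw thickness divided per ROI by a reference SD (the CN SD of a
#' reference center), and the w-score. Center differences are tested with a
#' paired two-sided t-test on subject-level means; the percent reduction of
#' the absolute difference after harmonization is reported per subject and
#' on the group mean.
#'
#' @param rawPair A [CohortExperiment] of the paired scans.
#' @param wPair The matching [WScoreExperiment].
#' @param refSd Per-ROI reference SD in mm (e.g. [referenceSd()] of the
#'   dominant center's CN scans).
#' @return List: `perSubject` data.frame, `rawP`, `wP` (paired t-test
#'   p-values), `meanReduction` (mean over subjects of the per-subject
#'   percent reduction), `aggregateReduction` (percent reduction of the
#'   mean absolute difference).
#' @export
intrasubjectComparison <- function(rawPair, wPair, refSd) {
    cid <- centerIds(rawPair)
    ids <- unique(cid)
    if (length(ids) != 2L) stop("rawPair must contain exactly two centers")
    subj <- subjectIds(rawPair)
    tab <- table(subj, cid)
    bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
    if (length(bad)) {
        stop("subject(s) without exactly one scan per center: ",
             paste(bad, collapse = ", "))
    }
    if (!identical(subjectIds(wPair), subj) ||
        !identical(centerIds(wPair), cid)) {
        stop("wPair does not match rawPair scan order")
    }
    refSd <- rep_len(refSd, length(roiNames(rawPair)))
    scaled <- sweep(thicknessMatrix(rawPair), 2L, refSd, `/`)
    wmat <- wscoreMatrix(wPair)
    us <- unique(subj)
    per <- data.frame(subject = us, raw_a = NA_real_, raw_b = NA_real_,
                      w_a = NA_real_, w_b = NA_real_)
    for (i in seq_along(us)) {
        ia <- which(subj == us[i] & cid == ids[1L])
        ib <- which(subj == us[i] & cid == ids[2L])
        per$raw_a[i] <- mean(scaled[ia, ])
        per$raw_b[i] <- mean(scaled[ib, ])
        per$w_a[i] <- mean(wmat[ia, ])
        per$w_b[i] <- mean(wmat[ib, ])
    }
    per$raw_diff <- per$raw_a - per$raw_b
    per$w_diff <- per$w_a - per$w_b
    per$reduction_pct <- 100 * (abs(per$raw_diff) - abs(per$w_diff)) /
        abs(per$raw_diff)
    rawP <- stats::t.test(per$raw_a, per$raw_b, paired = TRUE)$p.value
    wP <- stats::t.test(per$w_a, per$w_b, paired = TRUE)$p.value
    list(perSubject = per, rawP = rawP, wP = wP,
         centers = ids,
         meanReduction = mean(per$reduction_pct),
         aggregateReduction = 100 *
             (mean(abs(per$raw_diff)) - mean(abs(per$w_diff))) /
             mean(abs(per$raw_diff)))
}

#' Per-ROI CN reference SD
#'
#' @param cohort A [CohortExperiment].
#' @param center Center whose CN scans define the reference scale.
#' @return Named numeric, per-ROI SD in mm.
#' @export
referenceSd <- function(cohort, center) {
    sel <- centerIds(cohort) == center & diagnoses(cohort) == "CN"
    if (sum(sel) < 2L) stop("need >= 2 CN scans in center '", center, "'")
    apply(thicknessMatrix(cohort)[sel, , drop = FALSE], 2L, stats::sd)
}

#' Scalability of the LME harmonizer with the number of training centers
#'
#' Leave-one-center-out protocol: the reference is the model fitted on the
#' full cohort. For subsets of the remaining centers (all subsets per size,
#' optionally capped by random sampling), the model is refitted on the
#' subset's CN scans, the held-out test center is scored with the marginal
#' (unseen-center) policy, and the RMSE against the reference w-scores of
#' the test center — normalized by their pooled IQR — is averaged per
#' subset size.
#'
#' @param cohort A [CohortExperiment].
#' @param testCenter Center id held out for testing.
#' @param reference Optional [LMEModel] fitted on the full cohort.
#' @param maxSubsetsPerSize Cap on enumerated subsets per size
#'   (default all).
#' @param seed Seed for subset sampling when capped.
#' @return List: `perSize` data.frame (size, mean normalized RMSE, number
#'   of subsets), `perSubset` data.frame, `failed` character vector of
#'   failed subsets, `iqr` reference IQR.
#' @export
scalabilityExperiment <- function(cohort, testCenter, reference = NULL,
                                  maxSubsetsPerSize = Inf, seed = 1L) {
    ids <- unique(centerIds(cohort))
    if (length(ids) < 3L) stop("need >= 3 centers")
    if (!testCenter %in% ids) stop("unknown test center: ", testCenter)
    if (is.null(reference)) reference <- fitLME(cohort)
    testRows <- cohort[, centerIds(cohort) == testCenter]
    refW <- wscoreMatrix(scoreLME(reference, testRows))
    iqr <- stats::IQR(refW)
    others <- setdiff(ids, testCenter)
    rows <- list()
    failed <- character()
    for (size in seq_along(others)) {
        subsets <- utils::combn(others, size, simplify = FALSE)
        if (length(subsets) > maxSubsetsPerSize) {
            pick <- .withSeed(.streamSeed(seed, "subsets", testCenter, size),
                              sample(length(subsets), maxSubsetsPerSize))
            subsets <- subsets[pick]
        }
        for (S in subsets) {
            key <- paste(S, collapse = "+")
            w <- tryCatch({
                sub <- cohort[, centerIds(cohort) %in% S]
                m <- fitLME(sub, allowSingleCenter = TRUE)
                wscoreMatrix(scoreLME(m, testRows, policy = "marginal"))
            }, error = function(e) NULL)
            if (is.null(w)) {
                failed <- c(failed, key)
                next
            }
            rows[[length(rows) + 1L]] <- data.frame(
                size = size, subset = key,
                nrmse = sqrt(mean((w - refW)^2)) / iqr)
        }
    }
    perSubset <- do.call(rbind, rows)
    perSize <- do.call(rbind, lapply(split(perSubset, perSubset$size),
        function(df) data.frame(size = df$size[1L],
                                mean_nrmse = mean(df$nrmse),
                                n_subsets = nrow(df))))
    rownames(perSize) <- NULL
    list(perSize = perSize, perSubset = perSubset, failed = failed,
         iqr = iqr, testCenter = testCenter)
}

#' Group-mean atrophy table
#'
#' Mean w-score per ROI within each diagnosis group, sorted ascending (most
#' atrophic regions first) within group. On the w-score scale 0 is the
#' normative CN expectation, so negative group means express regional
#' atrophy.
#'
#' @param wscores A [WScoreExperiment].
#' @param path Optional CSV path to write the table to.
#' @return data.frame with columns `diagnosis`, `roi`, `mean_wscore`,
#'   `rank`.
#' @export
atrophyReport <- function(wscores, path = NULL) {
    dx <- as.character(diagnoses(wscores))
    w <- wscoreMatrix(wscores)
    if (!any(dx != "CN" | dx == "CN")) stop("empty input")
    out <- do.call(rbind, lapply(unique(dx), function(g) {
        m <- colMeans(w[dx == g, , drop = FALSE])
        o <- order(m)
        data.frame(diagnosis = g, roi = names(m)[o], mean_wscore = m[o],
                   rank = seq_along(m), row.names = NULL)
    }))
    if (!is.null(path)) {
        utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    }
    out
}
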