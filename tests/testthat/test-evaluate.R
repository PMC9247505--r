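test_that("PCA-LDA: perfect separation, null optimism band, Bayes-rate case", {
    set.seed(61)
    # two classes 10 SD apart on one feature: in-sample accuracy is 1
    X <- matrix(rnorm(200 * 10), 200, 10)
    X[1:100, 3] <- X[1:100, 3] + 10
    lab <- factor(rep(c("a", "b"), each = 100))
    r <- pcaLdaClassify(X, lab, nRepeats = 5, seed = 1)
    expect_equal(r@accuracy, 1.0)
    # identically distributed 68-dim classes: in-sample accuracy stays in
    # the null optimism band of the deliberately optimistic protocol
    X0 <- matrix(rnorm(1000 * 68), 1000, 68)
    lab0 <- factor(rep(c("a", "b"), each = 500))
    r0 <- pcaLdaClassify(X0, lab0, nRepeats = 10, seed = 2)
    expect_gt(r0@accuracy, 0.45)
    expect_lt(r0@accuracy, 0.60)
    # 1-D equal-variance Gaussians at distance 2 SD: accuracy -> Phi(1)
    n <- 4000
    X1 <- matrix(c(rnorm(n, 0), rnorm(n, 2)), ncol = 1)
    lab1 <- factor(rep(c("a", "b"), each = n))
    r1 <- pcaLdaClassify(X1, lab1, nRepeats = 5, seed = 3)
    expect_equal(r1@accuracy, pnorm(1), tolerance = 0.02)
})

test_that("classification result invariants hold", {
    set.seed(62)
    X <- matrix(rnorm(90 * 5), 90, 5)
    lab <- factor(rep(c("CN", "patient"), c(60, 30)))
    r <- pcaLdaClassify(X, lab, nRepeats = 7, seed = 4)
    expect_equal(r@accuracy, mean(r@perRepeat$accuracy))
    expect_equal(r@sensitivity, mean(r@perRepeat$sensitivity))
    expect_equal(r@nPerClass, 30L)              # undersampled to minority
    expect_equal(r@positiveClass, "patient")
    # deterministic under the same seed
    r2 <- pcaLdaClassify(X, lab, nRepeats = 7, seed = 4)
    expect_identical(r@perRepeat, r2@perRepeat)
    expect_error(pcaLdaClassify(X, factor(rep("a", 90))), "two levels")
    expect_error(
        pcaLdaClassify(X[1:62, ], factor(rep(c("CN", "p"), c(60, 2)))),
        "minority")
})

test_that("center prediction: pair count, near-chance nulls, skipping", {
    set.seed(63)
    # pure noise features, 4 centers: every pair stays near chance
    X <- matrix(rnorm(800 * 20), 800, 20)
    centers <- rep(c("A", "B", "C", "D"), each = 200)
    dx <- rep("CN", 800)
    cp <- centerPrediction(X, centers, dx, nRepeats = 10, seed = 5)
    expect_equal(nrow(cp$pairs), choose(4, 2))
    expect_true(all(cp$pairs$accuracy > 0.4 & cp$pairs$accuracy < 0.65))
    expect_true(is.na(diag(cp$accuracy)[1]))
    expect_equal(cp$accuracy["A", "B"], cp$accuracy["B", "A"])
    # 10 centers: 45 unordered pairs
    sim <- generateCohort(defaultDiscoveryConfig(scale = 0.05, seed = 64,
                                                 roi_names = dkRoiNames()[1:5]))
    cp10 <- centerPrediction(sim$cohort, nRepeats = 2, seed = 6)
    expect_equal(nrow(cp10$pairs), 45L)
    # a center below the minimum is skipped with a warning
    centers2 <- centers
    centers2[1:198] <- "B"
    msgs <- testthat::capture_warnings(
        centerPrediction(X, centers2, dx, nRepeats = 2, seed = 7,
                         minPerCenter = 3))
    expect_true(any(grepl("skipping", msgs)))
})

test_that("disease classification: permutation null and merged AD pooling", {
    sim <- generateCohort(defaultDiscoveryConfig(scale = 0.3, seed = 65,
                                                 roi_names = dkRoiNames()[1:8]))
    coh <- sim$cohort
    # shuffled labels: accuracy near chance per center
    set.seed(66)
    dxPerm <- sample(as.character(diagnoses(coh)))
    dc <- suppressWarnings(
        diseaseClassification(thicknessMatrix(coh), dxPerm, centerIds(coh),
                              nRepeats = 5, seed = 8))
    # small centers carry large in-sample optimism even under the null
    # (that is the point of the protocol); centers with >= 20 per class
    # stay near chance, the dominant center tightly so
    sizes <- vapply(dc$results, function(r) r@nPerClass, integer(1))
    expect_true(all(dc$perCenter$accuracy[sizes >= 20] < 0.75))
    d8 <- dc$perCenter$accuracy[dc$perCenter$center == "D8"]
    expect_gt(d8, 0.45)
    expect_lt(d8, 0.62)
    # merged set pools AD-bearing centers only (PD-only center excluded)
    m <- fitLME(coh)
    w <- scoreLME(m, coh)
    dc2 <- suppressWarnings(diseaseClassification(w, nRepeats = 5, seed = 9))
    expect_false(is.null(dc2$merged))
    dx <- as.character(diagnoses(coh))
    cid <- centerIds(coh)
    adCenters <- unique(cid[dx == "AD"])
    expect_false("D10" %in% adCenters)
    nPool <- sum(cid %in% adCenters & dx == "AD")
    expect_equal(dc2$merged@nPerClass, min(nPool,
        sum(cid %in% adCenters & dx == "CN")))
})

test_that("intrasubject comparison: identities, errors and reductions", {
    ct <- data.frame(id = c("A", "B"), n_cn = 30L, n_patient = 0L,
                     patient_dx = "AD", age_mean = 70, age_sd = 5,
                     sex_p = 0.5, edu_mean = 14, edu_sd = 3,
                     icv_mean = 1.4e6, icv_sd = 1.5e5)
    K <- 68
    cfg <- simConfig(ct, roi_names = dkRoiNames(),
                     center_additive = rbind(rep(0.25, K), rep(-0.25, K)),
                     center_scale = matrix(1, 2, K), noise_sd = 0.12,
                     severity_sd = 0, seed = 67)
    pair <- generatePairedCohort(cfg, 10, "A", "B")
    sim <- generateCohort(cfg)
    refSd <- referenceSd(sim$cohort, "A")
    # perfectly harmonized scores: per-subject reduction is 100%
    wHalf <- matrix(rnorm(10 * K), 10, K, dimnames = list(NULL, dkRoiNames()))
    wIdentical <- lmewscore:::.newWScoreExperiment(pair$cohort,
                                                   rbind(wHalf, wHalf))
    ic <- intrasubjectComparison(pair$cohort, wIdentical, refSd)
    expect_equal(ic$meanReduction, 100)
    expect_lt(ic$rawP, 0.05)
    # no center effect: nothing to remove, reduction stays small
    cfg0 <- simConfig(ct, roi_names = dkRoiNames(),
                      center_additive = matrix(0, 2, K),
                      center_scale = matrix(1, 2, K), noise_sd = 0.12,
                      severity_sd = 0, seed = 68)
    pair0 <- generatePairedCohort(cfg0, 40, "A", "B")
    sim0 <- generateCohort(cfg0)
    m0 <- fitLME(sim0$cohort)
    w0 <- scoreLME(m0, pair0$cohort)
    ic0 <- intrasubjectComparison(pair0$cohort, w0,
                                  referenceSd(sim0$cohort, "A"))
    expect_lt(abs(ic0$aggregateReduction), 20)
    # unpaired subject is an error listing the id
    broken <- pair$cohort[, -1]
    expect_error(
        intrasubjectComparison(broken, lmewscore:::.newWScoreExperiment(
            broken, wscoreMatrix(wIdentical)[-1, , drop = FALSE]), refSd),
        "pair_s001")
})

test_that("scalability: subset enumeration, endpoint identity, failure log", {
    ct <- data.frame(id = c("A", "B", "C", "D"), n_cn = 25L, n_patient = 0L,
                     patient_dx = "AD", age_mean = 70, age_sd = 5,
                     sex_p = 0.5, edu_mean = 14, edu_sd = 3,
                     icv_mean = 1.4e6, icv_sd = 1.5e5)
    cfg <- simConfig(ct, roi_names = sprintf("r%02d", 1:4), seed = 69,
                     severity_sd = 0)
    sim <- generateCohort(cfg)
    ref <- fitLME(sim$cohort)
    sc <- scalabilityExperiment(sim$cohort, "A", reference = ref, seed = 10)
    expect_equal(nrow(sc$perSubset), 2^3 - 1)
    expect_equal(sc$perSize$n_subsets, c(3L, 3L, 1L))
    # the size-3 endpoint equals the single leave-one-out model's error
    loo <- fitLME(sim$cohort[, centerIds(sim$cohort) != "A"])
    testRows <- sim$cohort[, centerIds(sim$cohort) == "A"]
    wLoo <- wscoreMatrix(scoreLME(loo, testRows, policy = "marginal"))
    wRef <- wscoreMatrix(scoreLME(ref, testRows))
    expect_equal(sc$perSize$mean_nrmse[3],
                 sqrt(mean((wLoo - wRef)^2)) / stats::IQR(wRef),
                 tolerance = 1e-10)
    # capping limits the number of subsets per size deterministically
    sc2 <- scalabilityExperiment(sim$cohort, "A", reference = ref,
                                 maxSubsetsPerSize = 2, seed = 11)
    expect_true(all(sc2$perSize$n_subsets <= 2))
    sc3 <- scalabilityExperiment(sim$cohort, "A", reference = ref,
                                 maxSubsetsPerSize = 2, seed = 11)
    expect_identical(sc2$perSubset, sc3$perSubset)
})

test_that("atrophy report ranks the seeded disease regions first", {
    cfg <- defaultDiscoveryConfig(scale = 0.3, seed = 71)
    sim <- generateCohort(cfg)
    m <- fitLME(sim$cohort)
    w <- scoreLME(m, sim$cohort)
    rep <- atrophyReport(w)
    adMap <- cfg$disease_atrophy$AD
    seeded <- names(adMap)[adMap < 0]
    top <- rep$roi[rep$diagnosis == "AD"][seq_along(seeded)]
    expect_gte(length(intersect(top, seeded)), length(seeded) - 2L)
    # CN means are near zero
    cnMeans <- rep$mean_wscore[rep$diagnosis == "CN"]
    expect_lt(max(abs(cnMeans)), 0.1)
    # disjoint atrophy maps give disjoint top regions
    pdMap <- cfg$disease_atrophy$PD
    pdSeeded <- names(pdMap)[pdMap < 0]
    pdTop <- rep$roi[rep$diagnosis == "PD"][seq_len(6)]
    expect_gt(length(intersect(pdTop, pdSeeded)), 3L)
    # CSV export
    path <- withr::local_tempfile(fileext = ".csv")
    atrophyReport(w, path = path)
    expect_true(file.exists(path))
    expect_equal(nrow(read.csv(path)), nrow(rep))
})
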