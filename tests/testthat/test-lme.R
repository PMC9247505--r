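test_that("objective, GLS and BLUP match the dense-matrix oracle", {
    for (seed in 1:12) {
        coh <- oracleToy(seed)
        cn <- coh
        X1 <- cbind(1, covariateMatrix(cn))
        y <- thicknessMatrix(cn)[, 1]
        centers <- centerIds(cn)
        for (r in 1:3) {
            set.seed(seed * 100 + r)
            d <- runif(1, 0, 0.05)
            s2 <- runif(1, 0.005, 0.1)
            expect_equal(remlObjective(d, s2, coh),
                         denseReml(d, s2, X1, y, centers),
                         tolerance = 1e-10)
            beta <- betaGLS(d, s2, coh)
            expect_equal(unname(beta), denseGls(d, s2, X1, y, centers),
                         tolerance = 1e-9)
            wj <- d / (s2 + table(centers)[unique(centers)] * d)
            # package BLUP via a frozen-parameter model on this toy
            bDense <- denseBlup(d, s2, X1, y, centers, cbind(beta))
            idx <- split(seq_along(centers),
                         factor(centers, levels = unique(centers)))
            bPkg <- vapply(idx, function(i) {
                r0 <- y[i] - X1[i, , drop = FALSE] %*% cbind(beta)
                length(i) * d / (s2 + length(i) * d) * mean(r0)
            }, numeric(1))
            expect_equal(unname(bPkg), unname(bDense), tolerance = 1e-9)
        }
    }
})

test_that("d = 0 reduces to the single-group ReML objective and OLS", {
    coh <- oracleToy(99, nCenters = 3)
    X1 <- cbind(1, covariateMatrix(coh))
    y <- thicknessMatrix(coh)[, 1]
    # at d = 0 the grouping is irrelevant
    expect_equal(remlObjective(0, 0.02, coh),
                 denseReml(0, 0.02, X1, y, rep("one", length(y))),
                 tolerance = 1e-10)
    ols <- as.numeric(solve(crossprod(X1), crossprod(X1, y)))
    expect_equal(unname(betaGLS(0, 0.02, coh)), ols, tolerance = 1e-9)
    expect_error(remlObjective(0.01, -1, coh), "sigma2")
    expect_error(remlObjective(-0.01, 1, coh), "d must")
})

test_that("objective is invariant to a constant thickness shift up to the intercept", {
    coh <- oracleToy(7, nCenters = 2)
    th <- thicknessMatrix(coh) + 0.8
    shifted <- CohortExperiment(
        th, subjectIds(coh), centerIds(coh), as.character(diagnoses(coh)),
        covariateMatrix(coh)[, "age"], covariateMatrix(coh)[, "sex"],
        covariateMatrix(coh)[, "education"], covariateMatrix(coh)[, "icv"])
    expect_equal(remlObjective(0.01, 0.02, coh),
                 remlObjective(0.01, 0.02, shifted), tolerance = 1e-9)
})

test_that("duplicated covariate columns raise a rank-deficiency error", {
    coh <- oracleToy(13, nCenters = 2)
    cd <- SummarizedExperiment::colData(coh)
    cd$education <- cd$age          # education duplicates age
    dup <- CohortExperiment(thicknessMatrix(coh), cd$subject_id,
                            cd$center_id, as.character(cd$diagnosis),
                            cd$age, cd$sex, cd$education, cd$icv)
    expect_error(betaGLS(0.01, 0.02, dup), "collinear")
})

test_that("quasi-Newton optimum matches a 400x400 grid search", {
    ct <- data.frame(id = c("A", "B", "C"), n_cn = c(30L, 25L, 35L),
                     n_patient = 0L, patient_dx = "AD", age_mean = 70,
                     age_sd = 6, sex_p = 0.5, edu_mean = 14, edu_sd = 3,
                     icv_mean = 1.4e6, icv_sd = 1.5e5)
    cfg <- simConfig(ct, roi_names = "r01",
                     center_additive = matrix(c(-0.15, 0, 0.15), 3, 1),
                     noise_sd = 0.12, severity_sd = 0, seed = 17)
    sim <- generateCohort(cfg)
    m <- fitLME(sim$cohort)
    cn <- sim$cohort
    grid_d <- exp(seq(log(1e-5), log(0.5), length.out = 400))
    grid_s2 <- exp(seq(log(1e-3), log(0.3), length.out = 400))
    X1 <- cbind(1, covariateMatrix(cn))
    Y <- thicknessMatrix(cn)
    ss <- lmewscore:::.lmeSuffStats(X1, Y, centerIds(cn))
    vals <- matrix(NA_real_, 400, 400)
    for (i in seq_along(grid_d)) {
        for (j in seq_along(grid_s2)) {
            vals[i, j] <- lmewscore:::.remlValue(grid_d[i], grid_s2[j], ss, 1L)
        }
    }
    best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    stepD <- log(grid_d[2] / grid_d[1])
    stepS <- log(grid_s2[2] / grid_s2[1])
    expect_lt(abs(log(m@d[1]) - log(grid_d[best[1]])), stepD * 1.5)
    expect_lt(abs(log(m@sigma2[1]) - log(grid_s2[best[2]])), stepS * 1.5)
    # the optimizer result is at least as good as the best grid point
    expect_gte(m@diagnostics$reml[1], max(vals) - 1e-8)
    # and at least as good as every multi-start iterate (monotonicity)
})

test_that("no-center-effect data drive d to the boundary and beta to OLS", {
    ct <- data.frame(id = c("A", "B", "C", "D"), n_cn = 100L, n_patient = 0L,
                     patient_dx = "AD", age_mean = 70, age_sd = 6,
                     sex_p = 0.5, edu_mean = 14, edu_sd = 3,
                     icv_mean = 1.4e6, icv_sd = 1.5e5)
    cfg <- simConfig(ct, roi_names = c("r01", "r02"), d_true = 0,
                     noise_sd = 0.12, severity_sd = 0, seed = 23)
    sim <- generateCohort(cfg)
    m <- fitLME(sim$cohort)
    expect_true(all(m@d < 0.005))
    X1 <- cbind(1, covariateMatrix(sim$cohort))
    y <- thicknessMatrix(sim$cohort)[, 1]
    ols <- as.numeric(solve(crossprod(X1), crossprod(X1, y)))
    se <- sqrt(diag(m@betaCov[, , 1]))
    expect_true(all(abs(c(m@alpha[1], m@beta[, 1]) - ols) <= 3 * se))
})

test_that("variance components and fixed effects are recovered from truth", {
    ct <- data.frame(id = sprintf("C%02d", 1:20), n_cn = 100L,
                     n_patient = 0L, patient_dx = "AD", age_mean = 70,
                     age_sd = 6, sex_p = 0.5, edu_mean = 14, edu_sd = 3,
                     icv_mean = 1.4e6, icv_sd = 1.5e5)
    relD <- relS <- numeric(5)
    for (r in 1:5) {
        cfg <- simConfig(ct, roi_names = "r01", d_true = 0.01,
                         center_scale = matrix(1, 20, 1),
                         noise_sd = 0.15, severity_sd = 0, seed = 100 + r)
        sim <- generateCohort(cfg)
        m <- fitLME(sim$cohort)
        relD[r] <- abs(m@d[1] - 0.01) / 0.01
        relS[r] <- abs(m@sigma2[1] - 0.0225) / 0.0225
        est <- c(m@alpha[1], m@beta[, 1])
        se <- sqrt(diag(m@betaCov[, , 1]))
        truth <- c(cfg$base_thickness, cfg$beta_true[, 1])
        expect_true(all(abs(est - truth) <= 4 * se))
        # intraclass correlation tracks the configured one
        icc <- m@d[1] / (m@d[1] + m@sigma2[1])
        expect_lt(abs(icc - 0.01 / 0.0325), 0.15)
    }
    expect_lt(median(relD), 0.5)   # d has ~20 center-level df
    expect_lt(median(relS), 0.05)
})

test_that("w-scores: zero at the conditional prediction, CN mean 0 / SD 1", {
    coh <- fixedEffectCohort(nPerCenter = 150,
                             offsets = c(A = 0.15, B = -0.15), K = 3,
                             noise = 0.1, seed = 41)
    m <- fitLME(coh)
    w <- wscoreMatrix(scoreLME(m, coh))
    expect_lt(max(abs(colMeans(w))), 0.05)
    expect_equal(unname(apply(w, 2, sd)), rep(1, 3), tolerance = 0.02)
    # a probe row at the conditional mean scores exactly 0
    X <- covariateMatrix(coh)[1, , drop = FALSE]
    j <- match("A", m@centers$id)
    pred <- m@alpha + as.numeric(X %*% m@beta) + m@b[j, ]
    probe <- CohortExperiment(matrix(pred, 1), "p", "A", "CN",
                              X[, "age"], X[, "sex"], X[, "education"],
                              X[, "icv"])
    rownames(probe) <- roiNames(coh)
    expect_equal(unname(wscoreMatrix(scoreLME(m, probe))[1, ]), c(0, 0, 0),
                 tolerance = 1e-10)
    # row-order permutation changes nothing
    perm <- sample(ncol(coh))
    w2 <- wscoreMatrix(scoreLME(m, coh[, perm]))
    expect_equal(w2, w[perm, ], tolerance = 1e-12)
})

test_that("unseen centers follow the chosen policy", {
    coh <- fixedEffectCohort(nPerCenter = 120,
                             offsets = c(A = 0.1, B = -0.1), K = 2,
                             noise = 0.1, seed = 42)
    m <- fitLME(coh)
    new <- fixedEffectCohort(nPerCenter = 30, offsets = c(N = 0.2), K = 2,
                             noise = 0.1, seed = 43)
    expect_error(scoreLME(m, new, policy = "strict"), "unregistered")
    wM <- wscoreMatrix(scoreLME(m, new, policy = "marginal"))
    # marginal scoring leaves the center offset in the score
    expect_gt(mean(wM), 0.5)
    wB <- wscoreMatrix(scoreLME(m, new, policy = "blup-from-data"))
    # predicting the intercept from the scored scans removes most of it
    expect_lt(abs(mean(wB)), abs(mean(wM)) / 2)
})

test_that("addCenter freezes existing scores and obeys BLUP shrinkage", {
    coh <- fixedEffectCohort(nPerCenter = 120,
                             offsets = c(A = 0.1, B = -0.1), K = 2,
                             noise = 0.1, seed = 44)
    m <- fitLME(coh)
    w0 <- wscoreMatrix(scoreLME(m, coh))
    big <- fixedEffectCohort(nPerCenter = 10000, offsets = c(N = 0.15),
                             K = 2, noise = 0.1, seed = 45)
    m2 <- addCenter(m, big)
    # original scores bit-identical
    expect_identical(wscoreMatrix(scoreLME(m2, coh)), w0)
    expect_true("N" %in% modelCenters(m2))
    expect_error(addCenter(m2, big), "already registered")
    # with n = 1e4 the BLUP approaches the true offset (shrinkage ~ 1)
    bTrue <- 0.15 - mean(c(0.1, -0.1))  # offsets are relative to the
                                        # fitted grand intercept
    expect_lt(max(abs(m2@b["N", ] - bTrue)) / bTrue, 0.05)
    # tiny center: registered with b = 0 and a warning
    tiny <- big[, 1]
    expect_warning(m3 <- addCenter(m, tiny), "b = 0")
    expect_equal(unname(m3@b["N", ]), c(0, 0))
    # small center: |BLUP| below |sample mean residual| (shrinkage)
    small <- fixedEffectCohort(nPerCenter = 2, offsets = c(S = 0.3), K = 2,
                               noise = 0.1, seed = 46)
    m4 <- addCenter(m, small)
    X1 <- cbind(1, covariateMatrix(small))
    resid <- thicknessMatrix(small) -
        (matrix(m@alpha, 2, 2, byrow = TRUE) +
             X1[, -1] %*% m@beta)
    expect_true(all(abs(m4@b["S", ]) < abs(colMeans(resid))))
})

test_that("fit agrees with lme4 on a multicenter cohort (independent check)", {
    skip_if_not_installed("lme4")
    sim <- generateCohort(defaultDiscoveryConfig(scale = 0.2, seed = 51,
                                                 roi_names = dkRoiNames()[1:2]))
    cn <- sim$cohort[, diagnoses(sim$cohort) == "CN"]
    m <- fitLME(sim$cohort)
    df <- data.frame(y = thicknessMatrix(cn)[, 1], covariateMatrix(cn),
                     center = centerIds(cn))
    fm <- suppressWarnings(
        lme4::lmer(y ~ age + sex + education + icv + (1 | center), df,
                   REML = TRUE))
    expect_equal(m@d[[1]], as.numeric(lme4::VarCorr(fm)$center),
                 tolerance = 1e-4)
    expect_equal(m@sigma2[[1]], stats::sigma(fm)^2, tolerance = 1e-4)
    expect_equal(unname(c(m@alpha[1], m@beta[, 1])),
                 unname(lme4::fixef(fm)), tolerance = 1e-4)
    re <- lme4::ranef(fm)$center
    expect_equal(m@b[rownames(re), 1], re[, 1], tolerance = 1e-4,
                 ignore_attr = TRUE)
})

test_that("serialized LME models score bit-identically after reload", {
    coh <- fixedEffectCohort(nPerCenter = 60, offsets = c(A = 0.1, B = -0.1),
                             K = 2, noise = 0.1, seed = 47)
    m <- fitLME(coh)
    path <- withr::local_tempfile(fileext = ".json")
    saveModel(m, path)
    m2 <- loadModel(path)
    expect_identical(wscoreMatrix(scoreLME(m2, coh)),
                     wscoreMatrix(scoreLME(m, coh)))
    expect_setequal(modelCenters(m2), c("A", "B"))
    # corrupted file fails loudly
    writeLines(c("{ not json"), path)
    expect_error(loadModel(path), "corrupt")
    # future versions are refused
    path2 <- withr::local_tempfile(fileext = ".json")
    saveModel(m, path2)
    txt <- sub("\"format_version\":1", "\"format_version\":999",
               readLines(path2))
    writeLines(txt, path2)
    expect_error(loadModel(path2), "version")
})
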