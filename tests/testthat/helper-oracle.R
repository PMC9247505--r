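# Dense-matrix oracles for the random-intercept model: every quantity is
# recomputed from an explicitly constructed n x n covariance matrix
# Sigma = sigma2 I + d Z Z', with no compound-symmetry shortcuts. Only for
# tiny problems (n <= a few hundred).

denseSigma <- function(d, sigma2, centers) {
    Z <- outer(centers, unique(centers), `==`) * 1
    sigma2 * diag(length(centers)) + d * tcrossprod(Z)
}

denseReml <- function(d, sigma2, X1, y, centers) {
    S <- denseSigma(d, sigma2, centers)
    Si <- solve(S)
    A <- t(X1) %*% Si %*% X1
    beta <- solve(A, t(X1) %*% Si %*% y)
    r <- y - X1 %*% beta
    as.numeric(
        -0.5 * determinant(S, logarithm = TRUE)$modulus -
        0.5 * determinant(A, logarithm = TRUE)$modulus -
        0.5 * t(r) %*% Si %*% r -
        0.5 * (length(y) - ncol(X1)) * log(2 * pi))
}

denseGls <- function(d, sigma2, X1, y, centers) {
    S <- denseSigma(d, sigma2, centers)
    Si <- solve(S)
    as.numeric(solve(t(X1) %*% Si %*% X1, t(X1) %*% Si %*% y))
}

denseBlup <- function(d, sigma2, X1, y, centers, beta) {
    ids <- unique(centers)
    vapply(ids, function(id) {
        sel <- centers == id
        Sj <- sigma2 * diag(sum(sel)) + d * matrix(1, sum(sel), sum(sel))
        as.numeric(d * colSums(solve(Sj, y[sel] - X1[sel, , drop = FALSE] %*% beta)))
    }, numeric(1))
}

# Random small cohort for oracle comparisons. Covariates on moderate scales
# (ICV expressed in 1e6 mm^3 units) keep the dense oracle itself
# well-conditioned; raw-unit robustness is exercised elsewhere.
oracleToy <- function(seed, nCenters = sample(1:3, 1), nPerCenter = NULL) {
    set.seed(seed)
    # keep every toy's total n comfortably above the 5 design parameters
    if (is.null(nPerCenter)) {
        nPerCenter <- sample(4:20, nCenters, replace = TRUE)
        if (sum(nPerCenter) < 12) nPerCenter <- nPerCenter + 12
    }
    n <- sum(nPerCenter)
    centers <- rep(sprintf("C%d", seq_len(nCenters)), nPerCenter)
    th <- matrix(2.5 + rnorm(n, 0, 0.3), n, 1,
                 dimnames = list(NULL, "roi01"))
    CohortExperiment(
        th, subject_id = sprintf("s%03d", seq_len(n)), center_id = centers,
        diagnosis = "CN", age = runif(n, 55, 85),
        sex = rbinom(n, 1, 0.5), education = runif(n, 8, 20),
        icv = runif(n, 1.2, 1.7))
}

# Small multicenter cohort with explicit, fixed center effects.
fixedEffectCohort <- function(nPerCenter = 40, offsets = c(A = 0.2, B = -0.2),
                              K = 4, noise = 0.1, seed = 1,
                              nPatient = 0, atrophy = -0.3) {
    set.seed(seed)
    ids <- names(offsets)
    rows <- list()
    for (j in seq_along(ids)) {
        n <- nPerCenter + nPatient
        age <- runif(n, 55, 85)
        sex <- rbinom(n, 1, 0.5)
        edu <- runif(n, 8, 20)
        icv <- rnorm(n, 1.4e6, 1.5e5)
        dx <- c(rep("CN", nPerCenter), rep("AD", nPatient))
        mu <- 2.5 - 0.005 * age - 0.03 * sex + 0.002 * edu + 5e-8 * icv +
            offsets[j]
        th <- matrix(mu, n, K) + matrix(rnorm(n * K, 0, noise), n, K)
        th[dx == "AD", ] <- th[dx == "AD", ] + atrophy
        rows[[j]] <- list(th = th, age = age, sex = sex, edu = edu,
                          icv = icv, dx = dx,
                          center = rep(ids[j], n),
                          subj = sprintf("%s_s%03d", ids[j], seq_len(n)))
    }
    th <- do.call(rbind, lapply(rows, `[[`, "th"))
    colnames(th) <- sprintf("roi%02d", seq_len(K))
    CohortExperiment(
        th,
        subject_id = unlist(lapply(rows, `[[`, "subj")),
        center_id = unlist(lapply(rows, `[[`, "center")),
        diagnosis = unlist(lapply(rows, `[[`, "dx")),
        age = unlist(lapply(rows, `[[`, "age")),
        sex = unlist(lapply(rows, `[[`, "sex")),
        education = unlist(lapply(rows, `[[`, "edu")),
        icv = unlist(lapply(rows, `[[`, "icv")))
}
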