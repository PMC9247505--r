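#' @include cohort-class.R utils.R
NULL

# Typical adult mean thickness (mm) per Desikan-Killiany parcel (one
# hemisphere; mirrored to both). Values are rounded normative magnitudes.
.DK_BASE34 <- c(
    bankssts = 2.45, caudalanteriorcingulate = 2.65,
    caudalmiddlefrontal = 2.55, cuneus = 1.90, entorhinal = 3.30,
    fusiform = 2.70, inferiorparietal = 2.45, inferiortemporal = 2.75,
    isthmuscingulate = 2.45, lateraloccipital = 2.20,
    lateralorbitofrontal = 2.65, lingual = 2.00, medialorbitofrontal = 2.45,
    middletemporal = 2.85, parahippocampal = 2.75, paracentral = 2.40,
    parsopercularis = 2.60, parsorbitalis = 2.70, parstriangularis = 2.50,
    pericalcarine = 1.65, postcentral = 2.05, posteriorcingulate = 2.50,
    precentral = 2.55, precuneus = 2.35, rostralanteriorcingulate = 2.85,
    rostralmiddlefrontal = 2.40, superiorfrontal = 2.70,
    superiorparietal = 2.20, superiortemporal = 2.80, supramarginal = 2.55,
    frontalpole = 2.70, temporalpole = 3.55, transversetemporal = 2.35,
    insula = 3.00)

.mirrorRoi <- function(x34) {
    out <- c(x34, x34)
    names(out) <- dkRoiNames()
    out
}

# Default covariate-effect matrix (mm per unit). Age-related thinning is
# graded by region: fastest in temporal/association cortex, slowest in
# primary sensory/occipital cortex.
.defaultBetaTrue <- function(roi_names) {
    temporal <- grepl(
        "temporal|entorhinal|fusiform|parahippocampal|insula|supramarginal|inferiorparietal",
        roi_names)
    sensory <- grepl(
        "pericalcarine|cuneus|lingual|lateraloccipital|postcentral|paracentral",
        roi_names)
    age <- ifelse(temporal, -0.009, ifelse(sensory, -0.003, -0.006))
    rbind(age = age, sex = rep(-0.04, length(roi_names)),
          education = rep(0.005, length(roi_names)),
          icv = rep(5e-8, length(roi_names)))
}

# Additive atrophy presets (mm, <= 0), concentrated in regions typically
# affected by each disease; mirrored over hemispheres.
.atrophyPreset <- function(disease, roi_names) {
    maps <- list(
        AD = c(entorhinal = -0.35, temporalpole = -0.28, fusiform = -0.22,
               inferiortemporal = -0.22, middletemporal = -0.20,
               parahippocampal = -0.18, inferiorparietal = -0.16,
               superiortemporal = -0.13, bankssts = -0.11, precuneus = -0.10),
        PD = c(precuneus = -0.13, fusiform = -0.11, supramarginal = -0.11,
               superiortemporal = -0.09, middletemporal = -0.08,
               lateraloccipital = -0.06))
    m <- maps[[disease]]
    out <- stats::setNames(numeric(length(roi_names)), roi_names)
    for (r in names(m)) {
        hit <- roi_names %in% paste0(c("lh_", "rh_"), r)
        out[hit] <- m[[r]]
    }
    out
}

#' Synthetic multicenter cohort configuration
#'
#' Defines the generative model of the synthetic cohorts: per-center group
#' sizes and covariate distributions, population covariate effects on
#' thickness, additive and multiplicative center effects, region-specific
#' disease atrophy, and the noise scale. Thickness of scan i in center j is
#'
#'   y_ik = base_k + X_i beta[,k] + add[j,k] + sev_i * atrophy[dx_i, k]
#'          + scale[j,k] * eps_ik,   eps_ik ~ N(0, noise_sd[k]^2)
#'
#' with `sev_i` a per-patient lognormal severity factor (mean 1; `sev_i = 1`
#' for CN or when `severity_sd = 0`). One global seed drives per-center,
#' per-stream substreams, so registering an extra center leaves every other
#' center's draws untouched.
#'
#' @param centers data.frame with one row per center: `id`, `n_cn`,
#'   `n_patient`, `patient_dx`, and CN covariate distribution columns
#'   `age_mean`, `age_sd`, `sex_p`, `edu_mean`, `edu_sd`, `icv_mean`,
#'   `icv_sd` (mm^3). Optional patient columns with suffix `_pt` default to
#'   the CN values. `edu_mean = NA` yields missing education for the center.
#' @param roi_names Character; defaults to the 68 Desikan-Killiany names.
#' @param base_thickness Named numeric per ROI (mm).
#' @param beta_true 4 x K matrix of covariate effects (rows `age`, `sex`,
#'   `education`, `icv`; mm per covariate unit).
#' @param d_true Per-ROI variance (mm^2) of the additive center effect used
#'   when `center_additive` is not supplied.
#' @param center_additive Optional J x K matrix of fixed additive center
#'   effects (mm); drawn `N(0, d_true)` per center otherwise.
#' @param center_scale Optional J x K matrix of multiplicative factors on the
#'   noise; drawn uniformly from `scale_range` otherwise.
#' @param scale_range Length-2 range of the multiplicative center effect.
#' @param disease_atrophy Named list, disease -> per-ROI additive effect
#'   (mm, <= 0). Defaults to the AD and PD presets.
#' @param severity_sd sdlog of the per-patient lognormal severity factor
#'   (mean 1, capped); 0 disables stage heterogeneity. The default 0.9
#'   emulates the clinical stage spectrum (mild to severe disease).
#' @param noise_sd Per-ROI residual SD (mm); defaults to a map increasing
#'   with base thickness (about 0.10-0.24 mm).
#' @param seed Integer master seed; fully determines the cohort.
#' @return A `CohortSimConfig` (validated list).
#' @seealso [generateCohort()], [defaultDiscoveryConfig()]
#' @export
simConfig <- function(centers, roi_names = dkRoiNames(),
                      base_thickness = NULL, beta_true = NULL,
                      d_true = 0.01, center_additive = NULL,
                      center_scale = NULL, scale_range = c(0.9, 1.1),
                      disease_atrophy = NULL, severity_sd = 0.9,
                      noise_sd = NULL, seed = 1L) {
    stopifnot(is.data.frame(centers), nrow(centers) >= 1L)
    need <- c("id", "n_cn", "n_patient", "age_mean", "age_sd", "sex_p",
              "edu_mean", "edu_sd", "icv_mean", "icv_sd")
    miss <- setdiff(need, names(centers))
    if (length(miss)) stop("centers is missing: ", paste(miss, collapse = ", "))
    if (anyDuplicated(centers$id)) stop("duplicate center ids")
    if (!"patient_dx" %in% names(centers)) centers$patient_dx <- "AD"
    for (cc in c("age_mean", "age_sd", "sex_p", "edu_mean", "edu_sd",
                 "icv_mean", "icv_sd")) {
        pt <- paste0(cc, "_pt")
        if (!pt %in% names(centers)) centers[[pt]] <- centers[[cc]]
    }
    K <- length(roi_names)
    if (is.null(base_thickness)) {
        dk <- .mirrorRoi(.DK_BASE34)[roi_names]
        dk[is.na(dk)] <- 2.5
        base_thickness <- dk
    }
    base_thickness <- rep_len(base_thickness, K)
    names(base_thickness) <- roi_names
    if (is.null(beta_true)) beta_true <- .defaultBetaTrue(roi_names)
    rownames(beta_true) <- .COVARIATE_NAMES
    colnames(beta_true) <- roi_names
    d_true <- rep_len(d_true, K)
    if (is.null(noise_sd)) {
        # thicker cortex varies more across subjects
        noise_sd <- pmax(0.10, 0.12 + 0.08 * (base_thickness - 2.0))
    }
    noise_sd <- rep_len(noise_sd, K)
    if (is.null(disease_atrophy)) {
        disease_atrophy <- list(AD = .atrophyPreset("AD", roi_names),
                                PD = .atrophyPreset("PD", roi_names))
    }
    disease_atrophy <- lapply(disease_atrophy, function(v) {
        v <- rep_len(v, K)
        names(v) <- roi_names
        if (any(v > 0)) stop("disease_atrophy must be <= 0 (mm)")
        v
    })
    fixmat <- function(m, what) {
        if (is.null(m)) return(NULL)
        m <- as.matrix(m)
        if (!all(dim(m) == c(nrow(centers), K))) {
            stop(what, " must be a centers x ROIs matrix")
        }
        dimnames(m) <- list(centers$id, roi_names)
        m
    }
    cfg <- structure(list(
        centers = centers, roi_names = roi_names,
        base_thickness = base_thickness, beta_true = beta_true,
        d_true = d_true,
        center_additive = fixmat(center_additive, "center_additive"),
        center_scale = fixmat(center_scale, "center_scale"),
        scale_range = scale_range, disease_atrophy = disease_atrophy,
        severity_sd = severity_sd, noise_sd = noise_sd,
        seed = as.integer(seed)), class = "CohortSimConfig")
    .validateSimConfig(cfg)
    cfg
}

# Severity factors are lognormal with mean 1, capped (at most 3x the mean
# atrophy) so a bounded disease stage cannot drive thickness negative.
.severityCap <- function(sdlog) min(exp(2.5 * sdlog), 3)

# Positivity check before any sampling: 3 SD adverse covariate excursions,
# center effects (fixed values or 4 sqrt(d_true)), deepest atrophy at the
# severity cap, and 4 SD of scaled noise must leave thickness positive.
.validateSimConfig <- function(cfg) {
    ct <- cfg$centers
    K <- length(cfg$roi_names)
    covLo <- rbind(
        age = max(ct$age_mean + 3 * ct$age_sd,
                  ct$age_mean_pt + 3 * ct$age_sd_pt),
        sex = 1,
        education = max(c(ct$edu_mean + 3 * ct$edu_sd,
                          ct$edu_mean_pt + 3 * ct$edu_sd_pt, 0), na.rm = TRUE),
        icv = max(ct$icv_mean + 3 * ct$icv_sd,
                  ct$icv_mean_pt + 3 * ct$icv_sd_pt))
    worstCov <- colSums(pmin(cfg$beta_true, 0) * as.numeric(covLo))
    atro <- Reduce(pmin, c(list(numeric(K)), cfg$disease_atrophy))
    sevMax <- if (cfg$severity_sd > 0) .severityCap(cfg$severity_sd) else 1
    scMax <- if (is.null(cfg$center_scale)) {
        max(cfg$scale_range)
    } else {
        max(cfg$center_scale)
    }
    # drawn center effects and noise are independent Gaussians: combine
    # their adverse excursions in quadrature; fixed effects enter linearly
    randSd2 <- (4 * scMax * cfg$noise_sd)^2
    addLo <- numeric(K)
    if (is.null(cfg$center_additive)) {
        randSd2 <- randSd2 + (3 * sqrt(cfg$d_true))^2
    } else {
        addLo <- apply(cfg$center_additive, 2L, min)
    }
    lo <- cfg$base_thickness + worstCov + addLo + sevMax * atro -
        sqrt(randSd2)
    if (any(lo <= 0)) {
        stop("config can produce non-positive thickness (worst case) for: ",
             paste(utils::head(cfg$roi_names[lo <= 0], 5L), collapse = ", "))
    }
    invisible(TRUE)
}

#' @export
print.CohortSimConfig <- function(x, ...) {
    cat(sprintf(
        "CohortSimConfig: %d center(s), %d ROIs, %d CN + %d patient scans, seed %d\n",
        nrow(x$centers), length(x$roi_names), sum(x$centers$n_cn),
        sum(x$centers$n_patient), x$seed))
    invisible(x)
}

#' Packaged 10-center discovery configuration
#'
#' A preset mimicking a published multicenter discovery collection: ten
#' centers with the group sizes and covariate moments of its demographic
#' table (one dominant center of 2907 CN scans, one PD-only patient center,
#' education confounded with center: per-center means range from about 9 to
#' 17 years). `scale` shrinks every group size proportionally (minimum 3).
#'
#' @param scale Multiplier on all group sizes.
#' @param seed Master seed.
#' @param roi_names ROI set (default: 68 Desikan-Killiany names).
#' @return A `CohortSimConfig` with 10 centers.
#' @export
defaultDiscoveryConfig <- function(scale = 1, seed = 1L,
                                   roi_names = dkRoiNames()) {
    ct <- data.frame(
        id = paste0("D", 1:10),
        n_cn = c(107L, 92L, 25L, 68L, 93L, 152L, 75L, 2907L, 51L, 71L),
        n_patient = c(96L, 48L, 16L, 34L, 74L, 75L, 56L, 351L, 64L, 120L),
        patient_dx = c(rep("AD", 9), "PD"),
        age_mean = c(76.15, 72.83, 74.76, 72.99, 76.03, 73.03, 74.65, 64.12,
                     64.24, 65.89),
        age_sd = c(4.56, 5.67, 3.57, 6.04, 5.79, 6.40, 7.92, 7.20, 11.30,
                   7.57),
        sex_p = c(0.51, 0.39, 0.72, 0.43, 0.45, 0.50, 0.28, 0.50, 0.53,
                  0.39),
        edu_mean = c(15.84, 16.48, 17.24, 16.63, 15.91, 16.74, 15.28, 12.76,
                     11.80, 12.79),
        edu_sd = c(3.01, 2.67, 2.20, 2.44, 2.76, 2.50, 2.73, 4.33, 4.84,
                   4.33),
        icv_mean = 1e5 * c(15.32, 14.32, 15.62, 14.96, 15.31, 15.01, 14.54,
                           12.48, 13.99, 12.24),
        icv_sd = 1e5 * c(1.54, 1.18, 1.18, 2.18, 1.73, 1.56, 1.59, 2.09,
                         1.86, 2.20),
        age_mean_pt = c(74.87, 74.50, 74.20, 72.54, 76.97, 75.73, 75.43,
                        71.21, 66.33, 64.70),
        age_sd_pt = c(7.84, 8.15, 9.20, 7.12, 7.20, 8.09, 6.55, 9.23, 10.09,
                      7.25),
        sex_p_pt = c(0.51, 0.60, 0.44, 0.47, 0.49, 0.60, 0.52, 0.32, 0.33,
                     0.49),
        edu_mean_pt = c(14.74, 15.48, 14.63, 15.76, 14.49, 15.96, 13.71,
                        9.17, 8.96, 10.70),
        edu_sd_pt = c(3.21, 2.91, 3.30, 2.88, 3.39, 2.58, 2.83, 5.59, 4.70,
                      5.03),
        icv_mean_pt = 1e5 * c(15.37, 14.60, 15.21, 15.29, 15.44, 15.43,
                              14.50, 13.87, 13.82, 13.08),
        icv_sd_pt = 1e5 * c(1.85, 1.65, 1.69, 2.34, 1.78, 1.65, 1.70, 2.00,
                            1.93, 2.21),
        stringsAsFactors = FALSE)
    if (scale != 1) {
        ct$n_cn <- pmax(3L, as.integer(round(ct$n_cn * scale)))
        ct$n_patient <- pmax(3L, as.integer(round(ct$n_patient * scale)))
    }
    simConfig(ct, roi_names = roi_names, seed = seed)
}

#' Build a generator configuration from a YAML or JSON file
#'
#' The file holds the [simConfig()] arguments: a `centers` table (list of
#' per-center records) plus any of the scalar/vector fields
#' (`roi_names`, `base_thickness`, `d_true`, `scale_range`, `severity_sd`,
#' `noise_sd`, `seed`, ...). Fields not present fall back to the package
#' defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `CohortSimConfig`.
#' @export
simConfigFromFile <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
            stop("reading YAML configs requires the 'yaml' package")
        }
        yaml::read_yaml(path)
    } else {
        jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(spec$centers)) stop("config must define 'centers'")
    centers <- if (is.data.frame(spec$centers)) {
        spec$centers
    } else {
        do.call(rbind, lapply(spec$centers, as.data.frame))
    }
    # YAML 1.1 reads exponents like 1.5e5 (no sign) as strings
    for (cc in setdiff(names(centers), c("id", "patient_dx"))) {
        centers[[cc]] <- as.numeric(centers[[cc]])
    }
    centers$id <- as.character(centers$id)
    args <- spec[setdiff(names(spec), "centers")]
    known <- setdiff(names(formals(simConfig)), "centers")
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    if (!is.null(args$beta_true)) args$beta_true <- as.matrix(args$beta_true)
    do.call(simConfig, c(list(centers = centers), args))
}

.drawCenterEffects <- function(cfg, id) {
    K <- length(cfg$roi_names)
    j <- match(id, cfg$centers$id)
    add <- cfg$center_additive
    sc <- cfg$center_scale
    .withSeed(.streamSeed(cfg$seed, "effects", id), {
        a <- stats::rnorm(K, 0, sqrt(cfg$d_true))
        s <- stats::runif(K, cfg$scale_range[1L], cfg$scale_range[2L])
        list(additive = if (is.null(add)) a else add[j, ],
             scale = if (is.null(sc)) s else sc[j, ])
    })
}

.drawCovariates <- function(n, pars, suffix = "") {
    g <- function(f) pars[[paste0(f, suffix)]]
    age <- pmax(40, stats::rnorm(n, g("age_mean"), g("age_sd")))
    sex <- stats::rbinom(n, 1L, g("sex_p"))
    edu <- if (is.na(g("edu_mean"))) {
        rep(NA_real_, n)
    } else {
        pmax(0, stats::rnorm(n, g("edu_mean"), g("edu_sd")))
    }
    icv <- pmax(8e5, stats::rnorm(n, g("icv_mean"), g("icv_sd")))
    cbind(age = age, sex = sex, education = edu, icv = icv)
}

.thicknessFor <- function(cfg, X, dx, eff) {
    K <- length(cfg$roi_names)
    n <- nrow(X)
    if (n == 0L) return(matrix(numeric(), 0L, K))
    Ximp <- X
    Ximp[is.na(Ximp)] <- 0  # NA education contributes no covariate effect
    mu <- matrix(cfg$base_thickness, n, K, byrow = TRUE) +
        Ximp %*% cfg$beta_true +
        matrix(eff$additive, n, K, byrow = TRUE)
    sev <- rep(1, n)
    if (cfg$severity_sd > 0) {
        sev <- pmin(stats::rlnorm(n, -cfg$severity_sd^2 / 2, cfg$severity_sd),
                    .severityCap(cfg$severity_sd))
    }
    for (d in names(cfg$disease_atrophy)) {
        hit <- dx == d
        if (any(hit)) {
            mu[hit, ] <- mu[hit, ] +
                sev[hit] %o% cfg$disease_atrophy[[d]]
        }
    }
    eps <- matrix(stats::rnorm(n * K, 0, rep(cfg$noise_sd, each = n)), n, K)
    mu + eps * matrix(eff$scale, n, K, byrow = TRUE)
}

#' Generate a synthetic multicenter cohort
#'
#' Draws covariates, center effects and thickness per the configuration's
#' generative model. The same configuration always reproduces the identical
#' cohort; per-center substreams make the draw for each center independent
#' of which other centers exist.
#'
#' @param cfg A `CohortSimConfig` from [simConfig()] or
#'   [defaultDiscoveryConfig()].
#' @return A `SyntheticCohort`: list with `cohort` (a [CohortExperiment])
#'   and `truth` (realized per-center additive/multiplicative effects and
#'   the generative parameters).
#' @export
generateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "CohortSimConfig"))
    .validateSimConfig(cfg)
    K <- length(cfg$roi_names)
    parts <- vector("list", nrow(cfg$centers))
    addMat <- matrix(NA_real_, nrow(cfg$centers), K,
                     dimnames = list(cfg$centers$id, cfg$roi_names))
    scMat <- addMat
    for (j in seq_len(nrow(cfg$centers))) {
        pars <- cfg$centers[j, ]
        id <- pars$id
        eff <- .drawCenterEffects(cfg, id)
        addMat[j, ] <- eff$additive
        scMat[j, ] <- eff$scale
        cn <- .withSeed(.streamSeed(cfg$seed, "cn", id), {
            X <- .drawCovariates(pars$n_cn, pars)
            list(X = X, th = .thicknessFor(cfg, X, rep("CN", pars$n_cn), eff))
        })
        pt <- .withSeed(.streamSeed(cfg$seed, "pt", id), {
            X <- .drawCovariates(pars$n_patient, pars, suffix = "_pt")
            list(X = X, th = .thicknessFor(
                cfg, X, rep(pars$patient_dx, pars$n_patient), eff))
        })
        nj <- pars$n_cn + pars$n_patient
        parts[[j]] <- list(
            X = rbind(cn$X, pt$X), th = rbind(cn$th, pt$th),
            dx = c(rep("CN", pars$n_cn), rep(pars$patient_dx, pars$n_patient)),
            center = rep(id, nj),
            subj = sprintf("%s_s%04d", id, seq_len(nj)))
    }
    X <- do.call(rbind, lapply(parts, `[[`, "X"))
    th <- do.call(rbind, lapply(parts, `[[`, "th"))
    colnames(th) <- cfg$roi_names
    cohort <- CohortExperiment(
        th,
        subject_id = unlist(lapply(parts, `[[`, "subj")),
        center_id = unlist(lapply(parts, `[[`, "center")),
        diagnosis = unlist(lapply(parts, `[[`, "dx")),
        age = X[, "age"], sex = X[, "sex"],
        education = X[, "education"], icv = X[, "icv"])
    structure(list(cohort = cohort,
                   truth = list(config = cfg, center_additive = addMat,
                                center_scale = scMat)),
              class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
    cat("SyntheticCohort with known ground truth\n")
    print(x$cohort)
    invisible(x)
}

#' Generate a paired two-center cohort (intrasubject design)
#'
#' Each subject is scanned once at `center_a` and once at `center_b` with
#' identical covariates and identical subject-level latent thickness; the
#' two rows differ only by the centers' additive/multiplicative effects and
#' independent noise. All subjects are CN.
#'
#' @param cfg A `CohortSimConfig`; both centers must be defined in it.
#' @param n_subjects Number of paired subjects (>= 2).
#' @param center_a,center_b Center ids from `cfg$centers$id`.
#' @return A `SyntheticCohort` with `2 * n_subjects` rows.
#' @export
generatePairedCohort <- function(cfg, n_subjects, center_a, center_b) {
    stopifnot(inherits(cfg, "CohortSimConfig"))
    if (n_subjects < 2L) stop("n_subjects must be >= 2 (paired statistics)")
    if (!all(c(center_a, center_b) %in% cfg$centers$id)) {
        stop("both centers must be defined in the config")
    }
    K <- length(cfg$roi_names)
    effA <- .drawCenterEffects(cfg, center_a)
    effB <- .drawCenterEffects(cfg, center_b)
    pars <- cfg$centers[match(center_a, cfg$centers$id), ]
    out <- .withSeed(.streamSeed(cfg$seed, "paired", center_a, center_b), {
        X <- .drawCovariates(n_subjects, pars)
        Ximp <- X
        Ximp[is.na(Ximp)] <- 0
        latent <- matrix(cfg$base_thickness, n_subjects, K, byrow = TRUE) +
            Ximp %*% cfg$beta_true
        noise <- function(eff) {
            e <- matrix(stats::rnorm(n_subjects * K, 0,
                                     rep(cfg$noise_sd, each = n_subjects)),
                        n_subjects, K)
            e * matrix(eff$scale, n_subjects, K, byrow = TRUE) +
                matrix(eff$additive, n_subjects, K, byrow = TRUE)
        }
        list(X = X, thA = latent + noise(effA), thB = latent + noise(effB))
    })
    th <- rbind(out$thA, out$thB)
    colnames(th) <- cfg$roi_names
    subj <- sprintf("pair_s%03d", seq_len(n_subjects))
    cohort <- CohortExperiment(
        th, subject_id = rep(subj, 2L),
        center_id = rep(c(center_a, center_b), each = n_subjects),
        diagnosis = "CN",
        age = rep(out$X[, "age"], 2L), sex = rep(out$X[, "sex"], 2L),
        education = rep(out$X[, "education"], 2L),
        icv = rep(out$X[, "icv"], 2L))
    structure(list(cohort = cohort,
                   truth = list(config = cfg,
                                center_additive = rbind(effA$additive,
                                                        effB$additive),
                                center_scale = rbind(effA$scale,
                                                     effB$scale))),
              class = "SyntheticCohort")
}
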