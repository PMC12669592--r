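# Synthetic cohort generator: latent 4-factor questionnaire structure, group
# trajectories over age / time since diagnosis, block missingness, genotype
# carriers and coupled imaging + clinical phenotypes, all with known ground
# truth for parameter-recovery tests.

#' Default item blocks for the 4-factor questionnaire battery
#'
#' 51 ordinal items in 11 questionnaire blocks with simple-structure loadings:
#' depressive symptoms and well-being on factor 1 (Depression), anxiety items
#' on factor 2 (Anxiety), childhood-trauma / post-traumatic stress / self-harm
#' items on factor 3 (Stress-Adversity), and alcohol-use, cannabis and
#' addiction items on factor 4 (ASRB). Well-being and one trauma item are
#' flagged reverse-coded, emulating instruments whose raw coding runs against
#' the construct.
#'
#' @return Data.frame with one row per item: `item`, `block`, `factor`,
#'   `loading`, `scale_min`, `scale_max`, `reverse`.
#' @export
default_item_blocks <- function() {
  blk <- function(block, n, factor, loadings, lo, hi, reverse = FALSE) {
    data.frame(
      item = sprintf("%s_%02d", block, seq_len(n)),
      block = block, factor = factor, loading = loadings,
      scale_min = lo, scale_max = hi,
      reverse = rep_len(reverse, n)
    )
  }
  rbind(
    blk("phq9",       9, 1, seq(0.55, 0.75, length.out = 9), 0, 3),
    blk("wellbeing",  4, 1, seq(0.45, 0.60, length.out = 4), 0, 5, reverse = TRUE),
    blk("loneliness", 2, 1, c(0.50, 0.55),                   0, 3),
    blk("gad7",       7, 2, seq(0.60, 0.78, length.out = 7), 0, 3),
    blk("panic",      2, 2, c(0.45, 0.50),                   0, 3),
    blk("cts",        5, 3, seq(0.55, 0.65, length.out = 5), 0, 4,
        reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    blk("ptsd",       6, 3, seq(0.50, 0.70, length.out = 6), 0, 4),
    blk("selfharm",   2, 3, c(0.40, 0.42),                   0, 2),
    blk("audit",     10, 4, seq(0.50, 0.75, length.out = 10), 0, 4),
    blk("cannabis",   2, 4, c(0.45, 0.48),                   0, 3),
    blk("addiction",  2, 4, c(0.35, 0.38),                   0, 2)
  )
}

#' Latent factor measurement model specification
#'
#' Defines the generating measurement model: pattern loadings, factor
#' correlation matrix, item uniquenesses, ordinal scale ranges and
#' discretisation thresholds. Defaults encode the 51-item / 11-block /
#' 4-factor battery of [default_item_blocks()] with unit-variance continuous
#' items (uniqueness `1 - loading^2`) and equiprobable standard-normal cut
#' points per item.
#'
#' @param blocks Item block table as returned by [default_item_blocks()].
#' @param loadings Optional n_items x k loading matrix overriding the
#'   simple-structure matrix built from `blocks`.
#' @param factor_corr k x k symmetric positive-definite factor correlation
#'   matrix with unit diagonal.
#' @param uniquenesses Per-item unique variances (>= 0). Default
#'   `1 - rowSums(loadings^2)` truncated below at 0.
#' @param thresholds Optional list of strictly increasing numeric cut points
#'   per item; default equiprobable `qnorm` cuts for the item's number of
#'   levels.
#' @param factor_names Character vector of factor labels.
#' @return Object of class `factor_model_spec`.
#' @export
factor_model_spec <- function(blocks = default_item_blocks(),
                              loadings = NULL,
                              factor_corr = default_factor_corr(),
                              uniquenesses = NULL,
                              thresholds = NULL,
                              factor_names = c("Depression", "Anxiety",
                                               "StressAdversity", "ASRB")) {
  k <- ncol(factor_corr)
  if (!is_spd(factor_corr) || any(abs(diag(factor_corr) - 1) > 1e-10)) {
    stop_npdim("factor_corr must be symmetric positive-definite with unit diagonal")
  }
  if (is.null(loadings)) {
    if (any(blocks$factor < 1 | blocks$factor > k)) {
      stop_npdim("blocks$factor indices must lie in 1..k (k = ", k, ")")
    }
    loadings <- matrix(0, nrow(blocks), k,
                       dimnames = list(blocks$item, factor_names[seq_len(k)]))
    loadings[cbind(seq_len(nrow(blocks)), blocks$factor)] <- blocks$loading
  } else {
    loadings <- as.matrix(loadings)
    if (is.null(rownames(loadings))) rownames(loadings) <- blocks$item
    if (is.null(colnames(loadings))) colnames(loadings) <- factor_names[seq_len(k)]
  }
  if (nrow(loadings) != nrow(blocks) || ncol(loadings) != k) {
    stop_npdim("loadings must be n_items x k")
  }
  comm <- rowSums((loadings %*% factor_corr) * loadings)
  if (any(comm > 1 + 1e-8)) {
    stop_npdim("loadings imply communality > 1 for items: ",
               paste(blocks$item[comm > 1 + 1e-8], collapse = ", "))
  }
  if (is.null(uniquenesses)) {
    uniquenesses <- pmax(0, 1 - comm)
  }
  uniquenesses <- rep_len(uniquenesses, nrow(blocks))
  if (any(uniquenesses < 0)) stop_npdim("uniquenesses must be >= 0")
  if (is.null(thresholds)) {
    thresholds <- lapply(seq_len(nrow(blocks)), function(i) {
      n_lev <- blocks$scale_max[i] - blocks$scale_min[i] + 1
      stats::qnorm(seq_len(n_lev - 1) / n_lev)
    })
    names(thresholds) <- blocks$item
  }
  for (i in seq_along(thresholds)) {
    th <- thresholds[[i]]
    if (length(th) > 1 && any(diff(th) <= 0)) {
      stop_npdim("thresholds must be strictly increasing for item ",
                 names(thresholds)[i])
    }
  }
  structure(list(blocks = blocks, loadings = loadings,
                 factor_corr = factor_corr, uniquenesses = uniquenesses,
                 thresholds = thresholds,
                 factor_names = factor_names[seq_len(k)]),
            class = "factor_model_spec")
}

#' @rdname factor_model_spec
#' @export
default_factor_corr <- function() {
  phi <- matrix(c(1.00, 0.55, 0.40, 0.15,
                  0.55, 1.00, 0.35, 0.10,
                  0.40, 0.35, 1.00, 0.10,
                  0.15, 0.10, 0.10, 1.00), 4, 4)
  dimnames(phi) <- list(c("Depression", "Anxiety", "StressAdversity", "ASRB"),
                        c("Depression", "Anxiety", "StressAdversity", "ASRB"))
  phi
}

#' Group trajectory specification
#'
#' Per-group latent factor means as a function of age (years) and, for
#' diagnosed groups, time since diagnosis (years; negative = pre-diagnosis).
#' The default set encodes: healthy controls flat at zero; cerebrovascular
#' disease flat but elevated on Depression and Stress-Adversity and slightly
#' lower Anxiety; Parkinson's disease with Depression rising steeply through
#' the pre-diagnostic window and continuing post-diagnosis, ASRB declining
#' with disease progression, and modest peri-diagnostic bumps in Anxiety and
#' Stress-Adversity.
#'
#' @param group Group label, e.g. "HC", "CVD", "PD".
#' @param factor_mean_fn `function(age, tsd)` returning an `length(age) x k`
#'   matrix of latent means; `tsd` is `NA` for never-diagnosed groups.
#' @param prevalence_split Fraction of diagnosed participants that are
#'   prevalent (diagnosed before questionnaire) rather than incident.
#' @param tsd_range Maximum |time since diagnosis| in years used when drawing
#'   diagnosis ages.
#' @return Object of class `group_trajectory_spec`.
#' @export
group_trajectory_spec <- function(group, factor_mean_fn,
                                  prevalence_split = 0.5, tsd_range = 12) {
  stopifnot(is.function(factor_mean_fn),
            prevalence_split >= 0, prevalence_split <= 1)
  structure(list(group = group, factor_mean_fn = factor_mean_fn,
                 prevalence_split = prevalence_split, tsd_range = tsd_range),
            class = "group_trajectory_spec")
}

#' @rdname group_trajectory_spec
#' @export
default_trajectory_specs <- function() {
  flat <- function(v) function(age, tsd) {
    matrix(v, length(age), 4, byrow = TRUE)
  }
  pd_fn <- function(age, tsd) {
    tsd0 <- ifelse(is.na(tsd), 0, tsd)
    cbind(
      0.20 + 0.50 * stats::plogis((tsd0 + 2) / 2),  # Depression ramps pre-dx
      0.05 + 0.10 * exp(-tsd0^2 / 32),              # Anxiety peri-dx bump
      0.12 + 0.15 * stats::plogis(tsd0 / 3),        # Stress-Adversity rises near dx
      -0.12 - 0.30 * stats::plogis(tsd0 / 3)        # ASRB declines with progression
    )
  }
  list(
    HC  = group_trajectory_spec("HC", flat(c(0, 0, 0, 0))),
    CVD = group_trajectory_spec("CVD", flat(c(0.25, -0.08, 0.15, 0.00)),
                                prevalence_split = 0.57),
    PD  = group_trajectory_spec("PD", pd_fn, prevalence_split = 0.42)
  )
}

#' Cohort-level specification
#'
#' Sample sizes, per-group age distributions, genotype carrier frequencies,
#' genotype effects on the latent factors, per-block missingness, imaging and
#' clinical couplings, and the seed. Defaults emulate a three-group
#' population cohort (HC / CVD / PD) with the diagnosed groups older than
#' controls, GBA1 carriers enriched in PD, rare APOE4 carriers, a negative
#' GBA1-carrier-by-age slope on the ASRB factor and a negative GBA1 main
#' effect on Stress-Adversity.
#'
#' @param n_per_group Named integer vector of participants per group.
#' @param age_distribution Named list `group -> c(mean, sd)` in years.
#' @param age_range Ages are truncated to this range (years).
#' @param carrier_freq Named list `genotype -> named per-group frequency`.
#' @param genotype_main Named list `genotype -> length-k main effect` on the
#'   latent factor means (carrier vs non-carrier).
#' @param genotype_age_interaction Named list `genotype -> length-k slope` per
#'   year of age (centred at `age_center`) in carriers.
#' @param age_center Centring constant (years) for genotype-age interactions.
#' @param missingness Named per-block probability that a participant skips the
#'   whole questionnaire block.
#' @param missingness_mode `"MCAR"` (default) or `"MAR"`; under MAR the
#'   block-skip probability increases with age via a logistic tilt.
#' @param imaging_coupling Data.frame of per-phenotype generative
#'   coefficients; see [default_imaging_coupling()]. `NULL` disables imaging.
#' @param clinical Logical; generate executive-task, grip-strength and
#'   reaction-time tables.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   bitwise.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 14000, CVD = 4600, PD = 1400),
                        age_distribution = list(HC = c(63.87, 7.65),
                                                CVD = c(68.47, 6.55),
                                                PD = c(69.45, 5.50)),
                        age_range = c(40, 80),
                        carrier_freq = list(
                          GBA1 = c(HC = 0.043, CVD = 0.044, PD = 0.068),
                          APOE4 = c(HC = 0.021, CVD = 0.024, PD = 0.020)),
                        genotype_main = list(
                          GBA1 = c(0, 0, -0.04, 0),
                          APOE4 = c(0, 0, 0, 0)),
                        genotype_age_interaction = list(
                          GBA1 = c(0, 0, 0, -0.04),
                          APOE4 = c(0, 0, 0, 0)),
                        age_center = 60,
                        missingness = NULL,
                        missingness_mode = c("MCAR", "MAR"),
                        imaging_coupling = default_imaging_coupling(),
                        clinical = TRUE,
                        seed = 1L) {
  missingness_mode <- match.arg(missingness_mode)
  if (any(n_per_group < 1)) stop_npdim("all group sizes must be >= 1")
  for (g in names(carrier_freq)) {
    f <- carrier_freq[[g]]
    if (any(f < 0 | f > 1)) stop_npdim("carrier frequencies must lie in [0, 1]")
  }
  structure(list(n_per_group = n_per_group,
                 age_distribution = age_distribution, age_range = age_range,
                 carrier_freq = carrier_freq, genotype_main = genotype_main,
                 genotype_age_interaction = genotype_age_interaction,
                 age_center = age_center,
                 missingness = missingness, missingness_mode = missingness_mode,
                 imaging_coupling = imaging_coupling, clinical = clinical,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default imaging phenotype coupling table
#'
#' Eight bilateral subcortical regions by three modalities (volume, T2*, QSM)
#' minus the substantia-nigra volume slot: 23 head-size-corrected phenotypes,
#' each generated as a linear combination of the latent factors, centred age
#' and a group offset plus unit-variance noise. Default non-zero couplings
#' follow the qualitative association pattern of interest: ASRB positively
#' coupled to substantia-nigra and putamen QSM, negatively to subcortical
#' volumes and striatal T2*; Depression negatively coupled to hippocampal and
#' amygdalar T2*; Stress-Adversity weakly to pallidal QSM; a positive PD
#' offset on substantia-nigra QSM and a negative one on hippocampal volume.
#'
#' @return Data.frame with columns `phenotype`, `region`, `modality`,
#'   `b_Depression`, `b_Anxiety`, `b_StressAdversity`, `b_ASRB`, `b_age`
#'   (per decade), `offset_PD`, `offset_CVD`, `noise_sd`.
#' @export
default_imaging_coupling <- function() {
  regions <- c("accumbens", "amygdala", "caudate", "hippocampus",
               "pallidum", "putamen", "thalamus", "substantia_nigra")
  grid <- expand.grid(region = regions,
                      modality = c("volume", "T2star", "QSM"),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$region == "substantia_nigra" & grid$modality == "volume"), ]
  cp <- data.frame(
    phenotype = paste(grid$region, grid$modality, sep = "_"),
    region = grid$region, modality = grid$modality,
    b_Depression = 0, b_Anxiety = 0, b_StressAdversity = 0, b_ASRB = 0,
    b_age = -0.10, offset_PD = 0, offset_CVD = 0, noise_sd = 1
  )
  set_b <- function(cp, region, modality, col, val) {
    i <- cp$region == region & cp$modality == modality
    cp[i, col] <- val
    cp
  }
  # ASRB: subcortical volume loss, striatal/nigral iron markers
  for (r in c("thalamus", "hippocampus", "pallidum", "putamen", "accumbens"))
    cp <- set_b(cp, r, "volume", "b_ASRB", -0.15)
  cp <- set_b(cp, "substantia_nigra", "QSM", "b_ASRB", 0.20)
  cp <- set_b(cp, "putamen", "QSM", "b_ASRB", 0.18)
  cp <- set_b(cp, "thalamus", "QSM", "b_ASRB", -0.15)
  cp <- set_b(cp, "putamen", "T2star", "b_ASRB", -0.15)
  cp <- set_b(cp, "caudate", "T2star", "b_ASRB", -0.12)
  # Depression: limbic T2* reductions
  cp <- set_b(cp, "hippocampus", "T2star", "b_Depression", -0.12)
  cp <- set_b(cp, "amygdala", "T2star", "b_Depression", -0.10)
  # Stress-Adversity: weak pallidal QSM coupling
  cp <- set_b(cp, "pallidum", "QSM", "b_StressAdversity", 0.08)
  # group offsets
  cp <- set_b(cp, "substantia_nigra", "QSM", "offset_PD", 0.60)
  cp <- set_b(cp, "hippocampus", "volume", "offset_PD", -0.30)
  cp
}

default_block_missingness <- function(blocks) {
  p <- rep(0.05, length(unique(blocks$block)))
  names(p) <- unique(blocks$block)
  p
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws participant covariates, diagnosis ages, genotypes and correlated
#' latent factor scores around group/age/time-to-diagnosis-dependent means,
#' maps them through the measurement model to ordinal questionnaire items
#' (optionally left continuous), applies block-structured missingness, and
#' attaches imaging and clinical phenotypes coupled to the latent truth.
#'
#' @param spec A [cohort_spec()].
#' @param model A [factor_model_spec()].
#' @param trajectories Named list of [group_trajectory_spec()] covering every
#'   group in `spec$n_per_group`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param discretise Map continuous item responses to ordinal levels via the
#'   model thresholds (default `TRUE`). When `FALSE` the items stay
#'   continuous, no reverse coding is applied and the item covariance equals
#'   `loadings %*% phi %*% t(loadings) + diag(uniquenesses)` in population.
#' @param apply_missingness Apply per-block missingness (default `TRUE`).
#' @return Object of class `synthetic_cohort` with elements `items`
#'   ([item_dataset()]), `latent_truth` (n x k matrix), `imaging`, `clinical`
#'   (data.frames or `NULL`) and `provenance` (specs + seed).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            model = factor_model_spec(),
                            trajectories = default_trajectory_specs(),
                            seed = spec$seed,
                            discretise = TRUE,
                            apply_missingness = TRUE) {
  groups <- names(spec$n_per_group)
  missing_traj <- setdiff(groups, names(trajectories))
  if (length(missing_traj)) {
    stop_npdim("no trajectory spec for group(s): ",
               paste(missing_traj, collapse = ", "))
  }
  set.seed(seed)
  k <- ncol(model$factor_corr)
  blocks <- model$blocks

  # --- covariates -----------------------------------------------------------
  cov_list <- lapply(groups, function(g) {
    n <- spec$n_per_group[[g]]
    ad <- spec$age_distribution[[g]]
    age <- pmin(pmax(stats::rnorm(n, ad[1], ad[2]), spec$age_range[1]),
                spec$age_range[2])
    f_frac <- c(HC = 0.554, CVD = 0.430, PD = 0.384)[g]
    if (is.na(f_frac)) f_frac <- 0.5
    data.frame(group = g, age = age,
               gender = stats::rbinom(n, 1, f_frac),
               education = pmin(pmax(stats::rnorm(n, 7.1, 3.1), 0), 20),
               centre = sample(1:3, n, replace = TRUE))
  })
  covariates <- do.call(rbind, cov_list)
  n_total <- nrow(covariates)
  covariates <- data.frame(participant_id = sprintf("P%06d", seq_len(n_total)),
                           covariates)

  # --- diagnosis ages / time since diagnosis --------------------------------
  covariates$age_at_diagnosis <- NA_real_
  for (g in groups) {
    ts <- trajectories[[g]]
    idx <- which(covariates$group == g)
    if (g == "HC") next
    n <- length(idx)
    prevalent <- stats::rbinom(n, 1, ts$prevalence_split) == 1
    tsd <- ifelse(prevalent,
                  stats::runif(n, 0, ts$tsd_range),
                  stats::runif(n, -ts$tsd_range, 0))
    dx <- pmax(covariates$age[idx] - tsd, 30)
    covariates$age_at_diagnosis[idx] <- dx
  }
  tsd_all <- covariates$age - covariates$age_at_diagnosis

  # --- genotypes ------------------------------------------------------------
  for (geno in names(spec$carrier_freq)) {
    fr <- spec$carrier_freq[[geno]]
    p <- fr[covariates$group]
    covariates[[paste0(tolower(geno), "_carrier")]] <-
      stats::rbinom(n_total, 1, unname(p))
  }

  # --- latent factor scores -------------------------------------------------
  mu <- matrix(0, n_total, k)
  for (g in groups) {
    idx <- which(covariates$group == g)
    mu[idx, ] <- trajectories[[g]]$factor_mean_fn(covariates$age[idx],
                                                  tsd_all[idx])
  }
  age_c <- covariates$age - spec$age_center
  for (geno in names(spec$carrier_freq)) {
    carrier <- covariates[[paste0(tolower(geno), "_carrier")]]
    main <- spec$genotype_main[[geno]] %||% rep(0, k)
    inter <- spec$genotype_age_interaction[[geno]] %||% rep(0, k)
    mu <- mu + outer(carrier, main) + outer(carrier * age_c, inter)
  }
  ch <- chol(model$factor_corr)
  latent <- mu + rmvnorm_chol(n_total, k, ch)
  colnames(latent) <- model$factor_names

  # --- items ----------------------------------------------------------------
  y <- latent %*% t(model$loadings) +
    matrix(stats::rnorm(n_total * nrow(blocks)), n_total) %*%
    diag(sqrt(model$uniquenesses), nrow(blocks))
  colnames(y) <- blocks$item

  if (discretise) {
    x <- y
    for (j in seq_len(ncol(y))) {
      th <- model$thresholds[[blocks$item[j]]]
      x[, j] <- findInterval(y[, j], th) + blocks$scale_min[j]
    }
    # instrument-style raw coding for reverse-flagged items
    rev_j <- which(blocks$reverse)
    for (j in rev_j) {
      x[, j] <- blocks$scale_min[j] + blocks$scale_max[j] - x[, j]
    }
    meta <- blocks[, c("item", "block", "scale_min", "scale_max", "reverse")]
  } else {
    x <- y
    meta <- data.frame(item = blocks$item, block = blocks$block,
                       scale_min = NA_real_, scale_max = NA_real_,
                       reverse = FALSE)
  }

  # --- block missingness ----------------------------------------------------
  miss <- spec$missingness %||% default_block_missingness(blocks)
  if (apply_missingness && any(miss > 0)) {
    for (b in names(miss)) {
      pb <- miss[[b]]
      if (pb <= 0) next
      if (spec$missingness_mode == "MAR") {
        # older participants skip more; tilt keeps the marginal rate near pb
        lp <- stats::qlogis(pmin(pmax(pb, 1e-6), 1 - 1e-6)) + 0.05 * age_c
        pvec <- stats::plogis(lp)
      } else {
        pvec <- rep(pb, n_total)
      }
      skip <- stats::rbinom(n_total, 1, pvec) == 1
      x[skip, blocks$block == b] <- NA
    }
  }

  items <- item_dataset(x, meta, covariates)

  # --- imaging phenotypes ---------------------------------------------------
  imaging <- NULL
  if (!is.null(spec$imaging_coupling)) {
    cp <- spec$imaging_coupling
    B <- t(as.matrix(cp[, paste0("b_", model$factor_names)]))
    vals <- latent %*% B
    vals <- vals + outer((covariates$age - spec$age_center) / 10, cp$b_age)
    vals <- vals + outer(covariates$group == "PD", cp$offset_PD)
    vals <- vals + outer(covariates$group == "CVD", cp$offset_CVD)
    vals <- vals + matrix(stats::rnorm(n_total * nrow(cp)), n_total) %*%
      diag(cp$noise_sd, nrow(cp))
    colnames(vals) <- cp$phenotype
    imaging <- data.frame(participant_id = covariates$participant_id, vals,
                          check.names = FALSE)
  }

  # --- clinical phenotypes --------------------------------------------------
  clinical <- NULL
  if (isTRUE(spec$clinical)) {
    clinical <- generate_clinical(covariates, latent, tsd_all, spec)
  }

  structure(list(items = items, latent_truth = latent,
                 imaging = imaging, clinical = clinical,
                 provenance = list(cohort_spec = spec, model_spec = model,
                                   trajectory_specs = trajectories,
                                   seed = as.integer(seed),
                                   discretise = discretise,
                                   apply_missingness = apply_missingness)),
            class = "synthetic_cohort")
}

# Executive tasks (one latent ability), grip strength and reaction time at
# two visits. Time-based tasks (reaction time, trail making) score higher =
# worse; dsst/tower higher = better.
generate_clinical <- function(covariates, latent, tsd, spec) {
  n <- nrow(covariates)
  age_c <- (covariates$age - spec$age_center) / 10
  pd <- covariates$group == "PD"
  f4 <- latent[, ncol(latent)]
  pre_dx <- !is.na(tsd) & tsd < 0
  # executive ability: declines with age; in PD, higher ASRB steepens the
  # pre-diagnostic decline; in HC higher ASRB is mildly beneficial
  g <- -0.35 * age_c +
    0.03 * f4 * (covariates$group == "HC") -
    0.15 * f4 * (pd & pre_dx) -
    0.25 * pd +
    stats::rnorm(n, 0, 0.8)
  g_z <- (g - mean(g)) / stats::sd(g)
  load_g <- c(rt = -0.80, trails = -0.85, dsst = 0.80, tower = 0.75)
  tasks <- sapply(names(load_g), function(t) {
    load_g[[t]] * g_z + stats::rnorm(n, 0, sqrt(1 - load_g[[t]]^2))
  })
  colnames(tasks) <- paste0("exec_", names(load_g))
  grip_v1 <- 30 - 2.0 * age_c - 2.5 * pd + 0.3 * f4 * !pd +
    stats::rnorm(n, 0, 4)
  grip_decl <- 1.5 + 1.8 * pd + 0.4 * pmax(f4, 0) + stats::rnorm(n, 0, 1.5)
  grip_v3 <- grip_v1 - grip_decl
  rt_v1 <- 550 + 25 * age_c + 25 * pd + stats::rnorm(n, 0, 60)
  rt_v3 <- rt_v1 + 20 + 8 * pd + stats::rnorm(n, 0, 40)
  data.frame(participant_id = covariates$participant_id, tasks,
             exec_ability = g_z,     # latent ground truth for recovery tests
             grip_v1 = grip_v1, grip_v3 = grip_v3,
             rt_v1 = rt_v1, rt_v3 = rt_v3, check.names = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$latent_truth),
      "| k =", ncol(x$latent_truth),
      "| seed =", x$provenance$seed, "\n")
  print(x$items)
  if (!is.null(x$imaging))
    cat("  imaging phenotypes:", ncol(x$imaging) - 1, "\n")
  if (!is.null(x$clinical))
    cat("  clinical measures:", ncol(x$clinical) - 1, "\n")
  invisible(x)
}

#' Extract the generating ground truth from a synthetic cohort
#'
#' Returns the exact generative quantities for parameter-recovery testing:
#' the loading matrix, factor correlation matrix, uniquenesses, true latent
#' scores and (where present) the imaging coupling coefficients and genotype
#' effects. Loadings are reported in construct orientation (before the raw
#' reverse coding applied to flagged instrument items).
#'
#' @param cohort A [generate_cohort()] result.
#' @return List with `loadings`, `phi`, `uniquenesses`, `scores`,
#'   `imaging_coupling` (`NULL` with `has_imaging = FALSE` when imaging was
#'   disabled), `genotype_main`, `genotype_age_interaction`.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  model <- cohort$provenance$model_spec
  spec <- cohort$provenance$cohort_spec
  list(loadings = model$loadings,
       phi = model$factor_corr,
       uniquenesses = model$uniquenesses,
       scores = cohort$latent_truth,
       has_imaging = !is.null(cohort$imaging),
       imaging_coupling = spec$imaging_coupling,
       genotype_main = spec$genotype_main,
       genotype_age_interaction = spec$genotype_age_interaction)
}
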