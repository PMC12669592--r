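test_that("identical specs and seeds reproduce cohorts bitwise", {
  a <- generate_cohort(cohort_spec(n_per_group = c(HC = 500, PD = 200), seed = 11))
  b <- generate_cohort(cohort_spec(n_per_group = c(HC = 500, PD = 200), seed = 11))
  expect_identical(a$items$items, b$items$items)
  expect_identical(a$latent_truth, b$latent_truth)
  expect_identical(a$imaging, b$imaging)
  expect_identical(a$clinical, b$clinical)
  c2 <- generate_cohort(cohort_spec(n_per_group = c(HC = 500, PD = 200), seed = 12))
  expect_false(identical(a$items$items, c2$items$items))
})

test_that("with no uniqueness and no discretisation the item covariance matches the closed form", {
  blocks <- default_item_blocks()
  m0 <- factor_model_spec(blocks, uniquenesses = rep(0, nrow(blocks)))
  sp <- cohort_spec(n_per_group = c(HC = 20000), imaging_coupling = NULL,
                    clinical = FALSE, seed = 3)
  co <- generate_cohort(sp, model = m0,
                        trajectories = default_trajectory_specs()["HC"],
                        discretise = FALSE, apply_missingness = FALSE)
  S <- cov(co$items$items)
  pop <- m0$loadings %*% m0$factor_corr %*% t(m0$loadings)
  expect_lt(max(abs((S - pop)[upper.tri(S)])), 0.03)
  # with uniquenesses restored, the diagonal converges to loadings^2 + psi
  m1 <- factor_model_spec(blocks)
  co1 <- generate_cohort(sp, model = m1,
                         trajectories = default_trajectory_specs()["HC"],
                         discretise = FALSE, apply_missingness = FALSE)
  S1 <- cov(co1$items$items)
  pop1 <- m1$loadings %*% m1$factor_corr %*% t(m1$loadings) +
    diag(m1$uniquenesses)
  expect_lt(max(abs(S1 - pop1)), 0.05)
})

test_that("realised block-missingness rate matches the specification", {
  blocks <- default_item_blocks()
  miss <- setNames(rep(0.2, 11), unique(blocks$block))
  sp <- cohort_spec(n_per_group = c(HC = 20000), missingness = miss,
                    imaging_coupling = NULL, clinical = FALSE, seed = 4)
  co <- generate_cohort(sp, trajectories = default_trajectory_specs()["HC"])
  for (b in unique(blocks$block)) {
    cols <- blocks$item[blocks$block == b]
    block_missing <- rowSums(is.na(co$items$items[, cols, drop = FALSE])) ==
      length(cols)
    expect_lt(abs(mean(block_missing) - 0.2), 0.01)
  }
})

test_that("carrier frequencies fall within binomial 99% bounds of the spec", {
  co <- generate_cohort(cohort_spec(seed = 5))
  spec <- co$provenance$cohort_spec
  cov <- co$items$covariates
  for (geno in names(spec$carrier_freq)) {
    col <- paste0(tolower(geno), "_carrier")
    for (g in names(spec$n_per_group)) {
      n <- sum(cov$group == g)
      p <- spec$carrier_freq[[geno]][[g]]
      obs <- sum(cov[[col]][cov$group == g])
      bounds <- qbinom(c(0.005, 0.995), n, p)
      expect_gte(obs, bounds[1])
      expect_lte(obs, bounds[2])
    }
  }
})

test_that("ground truth passes through the generating quantities", {
  co <- hc_cohort(2000, seed = 6)
  gt <- ground_truth(co)
  expect_identical(gt$loadings, co$provenance$model_spec$loadings)
  expect_identical(gt$phi, co$provenance$model_spec$factor_corr)
  expect_equal(nrow(gt$scores), 2000)
  # latent sample correlation approximates phi at large n
  big <- hc_cohort(20000, seed = 7)
  phi_hat <- cor(ground_truth(big)$scores)
  expect_lt(max(abs(phi_hat - ground_truth(big)$phi)), 0.03)
})

test_that("imaging can be disabled and is explicitly flagged", {
  sp <- cohort_spec(n_per_group = c(HC = 100), imaging_coupling = NULL,
                    clinical = FALSE, seed = 8)
  co <- generate_cohort(sp, trajectories = default_trajectory_specs()["HC"])
  expect_null(co$imaging)
  gt <- ground_truth(co)
  expect_false(gt$has_imaging)
  expect_null(gt$imaging_coupling)
})

test_that("invalid specifications are rejected with diagnostics", {
  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(factor_model_spec(factor_corr = bad_phi), "positive-definite")
  expect_error(cohort_spec(n_per_group = c(HC = 0)), ">= 1")
  expect_error(cohort_spec(carrier_freq = list(GBA1 = c(HC = 1.4))), "\\[0, 1\\]")
  blocks <- default_item_blocks()
  th <- factor_model_spec()$thresholds
  th[[1]] <- c(0.5, 0.1)
  expect_error(factor_model_spec(blocks, thresholds = th), "increasing")
  expect_error(
    generate_cohort(cohort_spec(n_per_group = c(HC = 10, XX = 10)),
                    trajectories = default_trajectory_specs()),
    "XX")
})

test_that("ordinal items respect their declared scale ranges and reverse flags", {
  co <- hc_cohort(3000, seed = 9)
  meta <- co$items$item_meta
  for (j in seq_len(ncol(co$items$items))) {
    v <- co$items$items[, j]
    expect_true(all(is.na(v) | (v >= meta$scale_min[j] & v <= meta$scale_max[j])))
  }
  # reverse-flagged items correlate negatively with their construct's
  # unflagged items in raw coding
  rev_item <- meta$item[meta$reverse & meta$block == "wellbeing"][1]
  raw <- cor(co$items$items[, c(rev_item, "phq9_01")],
             use = "complete.obs")[1, 2]
  expect_lt(raw, 0)
})

test_that("MAR missingness mode conditions block skipping on age", {
  blocks <- default_item_blocks()
  miss <- setNames(rep(0.2, 11), unique(blocks$block))
  sp <- cohort_spec(n_per_group = c(HC = 20000), missingness = miss,
                    missingness_mode = "MAR", imaging_coupling = NULL,
                    clinical = FALSE, seed = 10)
  co <- generate_cohort(sp, trajectories = default_trajectory_specs()["HC"])
  cols <- blocks$item[blocks$block == "audit"]
  skipped <- rowSums(is.na(co$items$items[, cols])) == length(cols)
  age <- co$items$covariates$age
  expect_gt(mean(age[skipped]), mean(age[!skipped]))
})
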