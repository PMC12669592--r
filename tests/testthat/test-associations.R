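test_that("partial correlation matches the residualise-then-correlate route", {
  set.seed(22)
  # empty covariate set equals plain Pearson exactly
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # 8-row constructed table against the two-stage oracle
  cv <- cbind(age = c(50, 52, 55, 58, 61, 64, 67, 70),
              edu = c(10, 12, 9, 16, 11, 14, 13, 15))
  x8 <- c(1.2, 0.4, 2.2, 1.8, 2.9, 2.1, 3.8, 3.0)
  y8 <- c(0.3, 0.9, 0.2, 1.4, 0.8, 1.9, 1.1, 2.2)
  got <- partial_correlation(x8, y8, as.data.frame(cv))
  want <- bf_partial_correlation(x8, y8, cv)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  # |t| = |r| sqrt(df / (1 - r^2)) identity
  expect_equal(abs(got$t), abs(got$r) * sqrt(got$df / (1 - got$r^2)))
  # outcome perfectly explained by covariates -> collinearity error
  y_lin <- 2 * cv[, "age"] - cv[, "edu"]
  expect_error(partial_correlation(x8, y_lin, as.data.frame(cv)),
               "collinearity")
  expect_error(partial_correlation(x8[1:4], y8[1:4], as.data.frame(cv)[1:4, ]),
               "n > n_covariates")
})

test_that("Bonferroni adjustment is exact and capped", {
  expect_equal(bonferroni(0.1, 1), 0.1)
  expect_equal(bonferroni(0.5, 92), 1.0)
  expect_equal(bonferroni(0.0005, 92), 0.046)
  expect_equal(bonferroni(c(0.01, 0.4), 10), c(0.1, 1))
  expect_warning(bonferroni(c(0.1, 0.2, 0.3), 2), "smaller")
  expect_error(bonferroni(1.2, 5), "\\[0, 1\\]")
})

test_that("linear contrasts equal the normal-equations solution", {
  # noise-free outcome = 2 * age
  d <- data.frame(age = c(50, 55, 60, 65, 70, 75),
                  gender = c(0, 1, 0, 1, 0, 1),
                  education = c(10, 12, 14, 9, 16, 11))
  d$y <- 2 * d$age
  tab <- suppressWarnings(linear_contrasts(d, "y"))  # perfect-fit warning
  expect_equal(tab$beta[tab$term == "age"], 2, tolerance = 1e-10)
  expect_lt(sum(residuals(attr(tab, "fit"))^2), 1e-16)
  # 10-row constructed design against the brute-force fit (age centred)
  set.seed(23)
  d10 <- data.frame(age = rnorm(10, 60, 5), gender = rbinom(10, 1, 0.5),
                    education = rnorm(10, 12, 2))
  d10$y <- 1 + 0.3 * d10$age - 0.5 * d10$gender + rnorm(10)
  tab10 <- linear_contrasts(d10, "y")
  X <- cbind(age = d10$age - mean(d10$age), gender = d10$gender,
             education = d10$education)
  want <- bf_lm(d10$y, X)
  expect_equal(tab10$beta, want$beta, tolerance = 1e-8)
  expect_equal(tab10$se, want$se, tolerance = 1e-8)
  expect_equal(tab10$t, want$t, tolerance = 1e-8)
  expect_equal(unique(tab10$df), want$df)
  # group contrasts are reference-vs-group with a declared reference
  d10$group <- rep(c("HC", "PD"), 5)
  d10$y2 <- d10$y + 2 * (d10$group == "PD")
  tabg <- linear_contrasts(d10, "y2", group = "group")
  expect_true("groupPD" %in% tabg$term)
  # aliased columns rejected by name
  d10$age_copy <- d10$age
  expect_error(linear_contrasts(d10, "y", covariates = c("age", "age_copy")),
               "age_copy")
})

test_that("genotype-by-age interaction uses centred age and recovers the slope", {
  set.seed(24)
  n <- 20000
  d <- data.frame(age = rnorm(n, 64, 7), gender = rbinom(n, 1, 0.5),
                  education = rnorm(n, 12, 3),
                  gba1_carrier = rbinom(n, 1, 0.3))
  d$f4 <- 0.1 - 0.04 * d$gba1_carrier * (d$age - mean(d$age)) + rnorm(n)
  tab <- linear_contrasts(d, "f4", genotype = "gba1_carrier",
                          genotype_age_interaction = TRUE)
  inter <- tab[tab$term == "gba1_carrier:age", ]
  expect_equal(nrow(inter), 1)
  expect_lt(abs(inter$beta - (-0.04)), 3 * inter$se)
  # centring keeps main effect and interaction nearly orthogonal
  fit <- attr(tab, "fit")
  mm <- model.matrix(fit)
  expect_lt(abs(cor(mm[, "gba1_carrier"], mm[, "age:gba1_carrier"])), 0.1)
})

test_that("executive composite behaves at the rank-1 and null extremes", {
  set.seed(25)
  # four perfectly correlated tasks: composite equals any single z-task
  g <- rnorm(300)
  tt <- data.frame(exec_rt = -g, exec_trails = -g, exec_dsst = g,
                   exec_tower = g)
  ec <- executive_composite(tt)
  z1 <- scale(g)[, 1]
  expect_lt(max(abs(ec$scores - z1 / sd(z1))), 1e-6)
  expect_equal(ec$sign_reversed, c("exec_rt", "exec_trails"))
  # independent tasks: null structure flagged with a warning
  t0 <- data.frame(exec_rt = rnorm(400), exec_trails = rnorm(400),
                   exec_dsst = rnorm(400), exec_tower = rnorm(400))
  expect_warning(ec0 <- executive_composite(t0), "little common variance")
  expect_equal(sd(ec0$scores), 1, tolerance = 1e-10)
  tt$exec_rt <- 1
  expect_error(executive_composite(tt), "zero-variance")
  # generator-coupled tasks: composite tracks the latent ability
  co <- hc_cohort(10000, seed = 26)
  cl <- co$clinical
  ec2 <- executive_composite(cl[, c("exec_rt", "exec_trails",
                                    "exec_dsst", "exec_tower")])
  expect_gt(cor(ec2$scores, cl$exec_ability), 0.9)
  # higher composite = better performance (dsst loads positively)
  expect_gt(cor(ec2$scores, cl$exec_dsst), 0)
  expect_lt(cor(ec2$scores, cl$exec_rt), 0)
})

test_that("imaging association grid derives its family size from the grid", {
  set.seed(27)
  n <- 400
  scores <- data.frame(F1 = rnorm(n))
  imaging <- data.frame(ph1 = scores$F1 * 0.5 + rnorm(n))
  covs <- data.frame(age = rnorm(n, 60, 7))
  # 1 factor x 1 phenotype: m = 1, adjusted = raw
  tab <- imaging_association_grid(scores, imaging, covs)
  expect_equal(attr(tab, "m"), 1)
  expect_equal(tab$p_adjusted, tab$p_raw)
  # full default grid: m = factors x phenotypes = 4 x 23 = 92
  co <- hc_cohort(3000, seed = 28)
  gt <- ground_truth(co)
  sc <- as.data.frame(gt$scores)
  covs2 <- co$items$covariates[, c("age", "gender", "education", "centre")]
  tab2 <- imaging_association_grid(sc, co$imaging[, -1], covs2)
  expect_equal(attr(tab2, "m"), 92)
  expect_equal(nrow(tab2), 92)
  expect_equal(tab2$p_adjusted, pmin(tab2$p_raw * 92, 1))
})

test_that("coupled and null imaging cells separate after adjustment", {
  # strong coupling detected: ASRB x substantia-nigra QSM at large n
  co <- hc_cohort(15000, seed = 29)
  sc <- as.data.frame(ground_truth(co)$scores)
  covs <- co$items$covariates[, c("age", "gender", "education", "centre")]
  tab <- imaging_association_grid(sc, co$imaging[, -1], covs)
  sn <- tab[tab$factor == "ASRB" & tab$phenotype == "substantia_nigra_QSM", ]
  expect_lt(sn$p_adjusted, 0.05)
  expect_gt(sn$r, 0)
  # zero-coupling generator: ~5% raw positives, none after adjustment
  cp0 <- default_imaging_coupling()
  cp0[, c("b_Depression", "b_Anxiety", "b_StressAdversity", "b_ASRB",
          "offset_PD", "offset_CVD")] <- 0
  co0 <- hc_cohort(2500, seed = 30, imaging_coupling = cp0)
  sc0 <- as.data.frame(ground_truth(co0)$scores)
  covs0 <- co0$items$covariates[, c("age", "gender", "education", "centre")]
  tab0 <- imaging_association_grid(sc0, co0$imaging[, -1], covs0)
  expect_lt(mean(tab0$p_raw < 0.05), 0.12)
  expect_equal(sum(tab0$significant), 0)
})

test_that("visit-change model matches the oracle and flags PD decline", {
  # identical visits -> all change coefficients zero
  set.seed(31)
  d <- data.frame(grip_v1 = rnorm(40, 30, 4), group = rep(c("HC", "PD"), 20),
                  f4 = rnorm(40), age = rnorm(40, 60, 5),
                  gender = rbinom(40, 1, 0.5))
  d$grip_v3 <- d$grip_v1
  tab0 <- visit_change_model(d, "grip_v1", "grip_v3", "f4")
  expect_true(all(abs(tab0$beta) < 1e-10))
  # 12-row constructed paired table against the normal-equations oracle
  d12 <- data.frame(
    grip_v1 = c(30, 32, 28, 35, 31, 29, 33, 27, 36, 30, 34, 26),
    grip_v3 = c(28, 31, 25, 34, 27, 28, 30, 22, 35, 28, 30, 24),
    group = rep(c("HC", "PD"), 6),
    f4 = c(0.5, -0.2, 1.1, -0.9, 0.3, 0.8, -1.2, 0.1, -0.4, 1.5, 0.2, -0.6),
    age = c(55, 60, 58, 63, 70, 52, 66, 59, 61, 64, 57, 68),
    gender = c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0))
  tab12 <- visit_change_model(d12, "grip_v1", "grip_v3", "f4")
  med <- median(d12$f4)
  X <- cbind(groupPD = as.numeric(d12$group == "PD"),
             above_median = as.numeric(d12$f4 > med),
             age = d12$age - mean(d12$age), gender = d12$gender)
  want <- bf_lm(d12$grip_v3 - d12$grip_v1, X)
  expect_equal(tab12$beta, want$beta, tolerance = 1e-8)
  expect_equal(tab12$se, want$se, tolerance = 1e-8)
  expect_equal(attr(tab12, "median_cut"), med)
  # generator: PD grip strength declines faster between visits
  co <- generate_cohort(cohort_spec(n_per_group = c(HC = 6000, PD = 2000),
                                    seed = 32, imaging_coupling = NULL))
  cl <- co$clinical
  dd <- data.frame(cl[, c("grip_v1", "grip_v3")],
                   group = co$items$covariates$group,
                   f4 = ground_truth(co)$scores[, "ASRB"],
                   age = co$items$covariates$age,
                   gender = co$items$covariates$gender)
  tabg <- visit_change_model(dd, "grip_v1", "grip_v3", "f4")
  pd_row <- tabg[tabg$term == "groupPD", ]
  expect_lt(pd_row$beta, 0)
  expect_lt(pd_row$p_raw, 0.001)
})
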