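test_that("reverse coding reflects flagged items and is an involution", {
  m <- rbind(c(2, 1), c(5, 0), c(NA, 3))
  ds <- make_item_dataset(m, lo = c(1, 0), hi = c(5, 3),
                          reverse = c(TRUE, TRUE))
  rc <- reverse_code(ds)
  expect_equal(rc$items[, 1], c(4, 1, NA))   # scale 1-5: 2 -> 4
  expect_equal(rc$items[, 2], c(2, 3, 0))    # scale 0-3: 0 -> 3
  expect_equal(reverse_code(rc)$items, ds$items)  # involution
  # unflagged items untouched
  ds2 <- make_item_dataset(m, lo = c(1, 0), hi = c(5, 3),
                           reverse = c(TRUE, FALSE))
  expect_equal(reverse_code(ds2)$items[, 2], m[, 2])
  # missing bounds rejected
  meta <- ds$item_meta; meta$scale_max[1] <- NA
  broken <- ds; broken$item_meta <- meta
  expect_error(reverse_code(broken), "without scale bounds")
})

test_that("composite scores sum items with strict missing propagation", {
  m <- matrix(3, nrow = 2, ncol = 9)           # PHQ-9-like at maximum
  m[2, 5] <- NA
  ds <- make_item_dataset(m, lo = 0, hi = 3, block = "phq9")
  cs <- composite_scores(ds)
  expect_equal(cs$phq9[1], 27)
  expect_true(is.na(cs$phq9[2]))
  lenient <- composite_scores(ds, strict = FALSE)
  expect_equal(lenient$phq9[2], 24)
  zeros <- make_item_dataset(matrix(0, 3, 4), lo = 0, hi = 3)
  expect_equal(composite_scores(zeros)$q1, c(0, 0, 0))
  # permutation invariance in item order
  perm <- sample(ncol(ds$items))
  cs_perm <- composite_scores(
    ds, scale_map = list(phq9 = colnames(ds$items)[perm]))
  expect_equal(cs_perm$phq9, cs$phq9)
  expect_error(composite_scores(ds, scale_map = list(empty = character(0))),
               "empty")
})

test_that("threshold trade-off reproduces the enumerated information scores", {
  # var A complete, var B missing for 50, var C missing for 90 (nested)
  n <- 100
  m <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  m[51:100, "B"] <- NA
  m[11:100, "C"] <- NA
  ds <- make_item_dataset(m, lo = NA, hi = NA)
  tr <- threshold_tradeoff(ds, grid = c(100, 50, 10))
  expect_equal(tr$grid$n_vars, c(1, 2, 3))
  expect_equal(tr$grid$complete_case_n, c(100, 50, 10))
  expect_equal(tr$grid$info_score, c(1 * 1.0, 2 * 0.5, 3 * 0.1))
  # tie between 1.0 and 1.0 broken toward more variables -> threshold 50
  expect_equal(tr$selected, 50)
  expect_setequal(tr$retained_vars, c("A", "B"))
})

test_that("degenerate trade-off cases follow the contract", {
  m <- matrix(rnorm(60), 20, 3)
  ds <- make_item_dataset(m, lo = NA, hi = NA)
  # single-element grid
  expect_equal(threshold_tradeoff(ds, 10)$selected, 10)
  # no missingness: all thresholds tie at v_max; smallest threshold returned
  tr <- threshold_tradeoff(ds, c(20, 15, 5))
  expect_equal(tr$selected, 5)
  expect_equal(length(tr$retained_vars), 3)
  # fractional grid converted to counts
  expect_equal(threshold_tradeoff(ds, 0.5)$grid$threshold, 10)
  # all variables dropped everywhere
  m2 <- matrix(NA_real_, 20, 3); m2[1, ] <- 1
  ds2 <- make_item_dataset(m2, lo = NA, hi = NA)
  expect_error(threshold_tradeoff(ds2, 10), "drops all variables")
  expect_error(threshold_tradeoff(ds, numeric(0)), "non-empty")
})

test_that("threshold trade-off equals exhaustive enumeration on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    p <- sample(3:10, 1)
    m <- matrix(rnorm(n * p), n, p)
    m[runif(n * p) < runif(1, 0, 0.5)] <- NA
    ds <- make_item_dataset(m, lo = NA, hi = NA)
    grid <- sort(sample(seq_len(n), sample(2:5, 1)))
    oracle <- bf_tradeoff(m, grid)
    if (max(oracle$table$n_vars) == 0) {
      expect_error(threshold_tradeoff(ds, grid), "drops all variables")
      next
    }
    got <- threshold_tradeoff(ds, grid)
    expect_equal(got$grid$n_vars, oracle$table$n_vars)
    expect_equal(got$grid$complete_case_n, oracle$table$complete_case_n)
    expect_equal(got$grid$info_score, oracle$table$info_score)
    expect_equal(got$selected, oracle$selected)
  }
})

test_that("complete-case filtering and zero-variance removal are idempotent", {
  m <- rbind(c(1, 2, 5), c(2, NA, 5), c(3, 1, 5), c(0, 0, 5))
  ds <- make_item_dataset(m, lo = 0, hi = 5)
  f1 <- drop_zero_variance(complete_case_filter(ds))
  expect_equal(nrow(f1$items), 3)          # row with NA dropped
  expect_equal(ncol(f1$items), 2)          # constant column dropped
  expect_equal(attr(f1, "removal_log")$vars_dropped, "it03")
  f2 <- drop_zero_variance(complete_case_filter(f1))
  expect_equal(f1$items, f2$items)
  # no missing, all variable -> identity
  clean <- make_item_dataset(matrix(c(1, 2, 3, 3, 1, 2), 3, 2), lo = 0, hi = 5)
  expect_equal(complete_case_filter(clean)$items, clean$items)
  # zero rows remaining rejected
  allna <- make_item_dataset(matrix(NA_real_, 3, 2), lo = NA, hi = NA)
  expect_error(complete_case_filter(allna), "every participant")
})

test_that("standardisation supports own and reference statistics", {
  m <- matrix(rnorm(200, mean = 5, sd = 2), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  st <- standardize_items(m)
  expect_equal(unname(colMeans(st$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(st$z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # location invariance
  st2 <- standardize_items(m + 10)
  expect_equal(st$z, st2$z, tolerance = 1e-12)
  # reference stats from group A applied to shifted group B
  b <- m + 1
  zb <- standardize_items(b, reference_stats = st$stats)$z
  expect_true(all(colMeans(zb) > 0))
  expect_equal(unname(colMeans(zb)), 1 / unname(st$stats$sd), tolerance = 1e-12)
  const <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2)
  expect_error(standardize_items(const), "zero or non-finite SD")
})
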