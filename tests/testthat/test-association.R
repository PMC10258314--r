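test_that("percentage volume change follows the baseline-relative formula", {
  expect_identical(tumor_volume_change(28.4, 28.4), 0)
  expect_identical(tumor_volume_change(14.2, 28.4), -50)
  expect_identical(tumor_volume_change(56.8, 28.4), 100)
  expect_error(tumor_volume_change(10, 0), "v_tp0")
  # scale invariance
  set.seed(3)
  for (i in 1:10) {
    v1 <- runif(1, 0, 100); v0 <- runif(1, 0.1, 100)
    c0 <- runif(1, 0.01, 50)
    expect_equal(tumor_volume_change(v1, v0),
                 tumor_volume_change(c0 * v1, c0 * v0), tolerance = 1e-10)
  }
})

test_that("Spearman correlation hits the monotone extremes", {
  x <- c(1, 2, 5, 9, 12)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
  expect_warning(r <- spearman_correlation(x, rep(2, 5)), "constant")
  expect_true(is.na(r$rho))
  expect_error(spearman_correlation(1:5, 1:4), "length")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearman_correlation(x, y)$rho
    expect_equal(spearman_correlation(exp(x), y)$rho, r0, tolerance = 1e-12)
    expect_equal(spearman_correlation(x, y^3)$rho, r0, tolerance = 1e-12)
  }
})

test_that("Spearman null distribution is centred at zero", {
  set.seed(29)
  rhos <- replicate(300, spearman_correlation(runif(61), runif(61))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("Cramer's V matches hand-computed contingency oracles", {
  cv <- cramers_v(matrix(c(20, 5, 5, 20), 2))
  expect_equal(cv$chi_squared, 18, tolerance = 1e-12)
  expect_equal(cv$v, 0.6, tolerance = 1e-12)

  perfect <- cramers_v(rep(c("a", "b"), each = 25),
                       rep(c("x", "y"), each = 25))
  expect_equal(perfect$v, 1, tolerance = 1e-12)

  balanced <- cramers_v(matrix(c(25, 25, 25, 25), 2))
  expect_equal(balanced$v, 0, tolerance = 1e-12)

  expect_warning(r <- cramers_v(rep("a", 10), rep(c("x", "y"), 5)),
                 "levels")
  expect_true(is.na(r$v))
})

test_that("Cramer's V is invariant to category relabeling and lies in [0,1]", {
  set.seed(17)
  for (i in 1:25) {
    a <- sample(letters[1:3], 60, replace = TRUE)
    b <- sample(LETTERS[1:4], 60, replace = TRUE)
    v1 <- suppressWarnings(cramers_v(a, b)$v)
    perm <- stats::setNames(c("q", "r", "s"), letters[1:3])
    v2 <- suppressWarnings(cramers_v(perm[a], b)$v)
    expect_equal(v1, v2, tolerance = 1e-12)
    expect_true(v1 >= 0 && v1 <= 1)
  }
})

test_that("coefficients agree with an independent rank/chi-squared route", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(spearman_correlation(x, y)$rho,
                 stats::cor(rank(x), rank(y)), tolerance = 1e-10)
  }
  for (i in 1:50) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - expected)^2 / expected)
    expect_equal(cramers_v(tab)$v, sqrt(chi2 / sum(tab)),
                 tolerance = 1e-10)
  }
})

test_that("interpretation bands label coefficients as configured", {
  expect_identical(interpret_coefficient(0.78, "spearman"), "strong")
  expect_identical(interpret_coefficient(0.52, "spearman"), "moderate")
  expect_identical(interpret_coefficient(-0.85, "spearman"), "very strong")
  expect_identical(interpret_coefficient(0, "spearman"), "negligible")
  expect_identical(interpret_coefficient(0.32, "cramers_v"), "very strong")
  expect_identical(interpret_coefficient(0.12, "cramers_v"), "moderate")
  custom <- data.frame(threshold = c(0.5, 0), label = c("high", "low"))
  expect_identical(interpret_coefficient(0.6, guideline = custom), "high")
})

test_that("the waterfall table sorts descending with stable ties", {
  coh <- tiny_cohort()
  fits <- compute_cohort_growth_rates(coh)
  expect_message(wf <- waterfall_table(coh, fits), "excluded")
  expect_equal(wf$patient_id, "P1")  # only P1 has TP+1
  expect_equal(wf$pct_change, tumor_volume_change(10, 20))

  # synthetic ties: equal pct_change ordered by patient id
  les <- tiny_lesions()
  les <- rbind(les, data.frame(patient_id = c("P2", "P3"),
                               timepoint = "TP+1",
                               lesion_id = "L01",
                               volume_cc = c(14.2, 14.2),
                               site = "liver"))
  coh2 <- load_cohort(les, tiny_patients())
  wf2 <- waterfall_table(coh2, compute_cohort_growth_rates(coh2))
  expect_equal(wf2$pct_change, rep(-50, 3))
  expect_equal(wf2$patient_id, c("P1", "P2", "P3"))
})

test_that("the validation panel wires alpha to response and covariates", {
  coh <- generate_cohort(cohort_config(seed = 4))
  fits <- compute_cohort_growth_rates(coh)
  tab <- validate_alpha(coh, fits)
  expect_true(all(c("volume_change_tp1", "n_metastases", "met_liver",
                    "primary_site") %in% tab$variable))
  sp <- tab[tab$method == "spearman", ]
  expect_true(all(abs(sp$coefficient) <= 1))
  cv <- tab[tab$method == "cramers_v", ]
  expect_true(all(cv$coefficient >= 0 & cv$coefficient <= 1, na.rm = TRUE))
  # alpha correlates positively with early volume change and lesion count
  expect_gt(sp$coefficient[sp$variable == "volume_change_tp1"], 0.3)
  expect_gt(sp$coefficient[sp$variable == "n_metastases"], 0.2)
})
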