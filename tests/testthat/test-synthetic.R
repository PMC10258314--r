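test_that("generated cohorts have the configured structure and validate", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_s3_class(coh, "tumor_cohort")
  expect_equal(nrow(coh$patients), 86)
  n_dn <- sum(coh$patients$de_novo)
  expect_true(n_dn > 25 && n_dn < 60)  # binomial(86, 0.51)
  # de novo patients have no TP-1 rows
  dn <- coh$patients$patient_id[coh$patients$de_novo]
  expect_false(any(coh$lesions$patient_id %in% dn &
                     coh$lesions$timepoint == "TP-1"))
  # endpoint ordering invariants
  expect_true(all(coh$patients$pfs_days <= coh$patients$os_days))
  expect_true(all(coh$patients$pfs_days <= coh$patients$pfs2_days))
  # written files reload identically
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  coh2 <- load_cohort(paths[["lesions"]], paths[["patients"]])
  expect_identical(coh2$lesions$volume_cc, coh$lesions$volume_cc)
})

test_that("the same seed reproduces the cohort and seeds are substreams", {
  c1 <- generate_cohort(cohort_config(n_patients = 20, seed = 99))
  c2 <- generate_cohort(cohort_config(n_patients = 20, seed = 99))
  expect_identical(c1$lesions, c2$lesions)
  expect_identical(c1$patients, c2$patients)
  expect_identical(attr(c1, "truth"), attr(c2, "truth"))
  # extending the cohort leaves existing patients untouched
  c3 <- generate_cohort(cohort_config(n_patients = 30, seed = 99))
  expect_equal(c3$patients[1:20, ], c1$patients, ignore_attr = TRUE)
  # a different seed reshuffles
  c4 <- generate_cohort(cohort_config(n_patients = 20, seed = 100))
  expect_false(identical(c4$patients$os_days, c1$patients$os_days))
})

test_that("noise-free volumes reproduce the true growth rate exactly", {
  coh <- generate_cohort(cohort_config(seed = 12, sigma_v = 0))
  truth <- attr(coh, "truth")
  fits <- compute_cohort_growth_rates(coh)
  measured <- !truth$de_novo
  expect_equal(fits$alpha[match(truth$patient_id[measured],
                                fits$patient_id)],
               truth$alpha[measured], tolerance = 1e-10)
})

test_that("lesion splits conserve total volume with positive parts", {
  expect_identical(generate_lesion_split(28.4, 1), 28.4)
  v <- generate_lesion_split(28.4, 7, seed = 5)
  expect_length(v, 7)
  expect_true(all(v > 0))
  expect_equal(sum(v), 28.4, tolerance = 1e-9)
  expect_error(generate_lesion_split(28.4, 0), "n_lesions")
  expect_error(generate_lesion_split(-1, 3), "total_volume")
})

test_that("cohort summaries reproduce the descriptive-table structure", {
  coh <- generate_cohort(cohort_config(seed = 2))
  sm <- summarize_cohort(coh)
  expect_identical(sm$quantity,
                   c("baseline_volume_cc", "n_metastases_baseline",
                     "tp_minus1_interval_days", "alpha_per_day"))
  expect_true(all(sm$median >= sm$min & sm$median <= sm$max))
  # a single-patient cohort summarizes to that patient's values
  one <- generate_cohort(cohort_config(n_patients = 1, seed = 3))
  sm1 <- summarize_cohort(one)
  expect_equal(sm1$median[1], one$timelines[[1]]$total_volumes[["TP0"]])
  expect_equal(sm1$median[2], one$patients$n_met_baseline[1])
})

test_that("generator medians stay near the reference cohort across seeds", {
  vm <- am <- numeric(40)
  for (s in seq_len(40)) {
    coh <- generate_cohort(cohort_config(seed = 700 + s))
    sm <- summarize_cohort(coh)
    vm[s] <- sm$median[sm$quantity == "baseline_volume_cc"]
    am[s] <- sm$median[sm$quantity == "alpha_per_day"]
  }
  expect_gt(median(vm), 14); expect_lt(median(vm), 57)
  expect_gt(median(am), 0.024); expect_lt(median(am), 0.094)
})

test_that("noisy estimation error stays within the propagation bound", {
  # alpha_hat - alpha = (e0 - e_pre) / interval with e ~ N(0, sigma_v^2)
  errs <- bounds <- numeric(20)
  for (s in seq_len(20)) {
    coh <- generate_cohort(cohort_config(seed = 880 + s, sigma_v = 0.2))
    truth <- attr(coh, "truth")
    fits <- compute_cohort_growth_rates(coh)
    m <- !truth$de_novo
    err <- abs(fits$alpha[match(truth$patient_id[m], fits$patient_id)] -
                 truth$alpha[m])
    iv <- abs(coh$patients$tp_minus1_offset_days[
      match(truth$patient_id[m], coh$patients$patient_id)])
    errs[s] <- median(err)
    bounds[s] <- 2 * 0.2 / median(iv)
  }
  expect_true(all(errs <= bounds))
})

test_that("invalid configurations are rejected with all violations listed", {
  expect_error(cohort_config(de_novo_fraction = 1.5), "de_novo_fraction")
  expect_error(cohort_config(volume_range = c(10, 1)), "volume_range")
  err <- tryCatch(cohort_config(sigma_v = -1, met_alpha_corr = 2),
                  error = conditionMessage)
  expect_match(err, "sigma_v")
  expect_match(err, "met_alpha_corr")
})
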