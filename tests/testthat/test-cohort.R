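test_that("a well-formed fixture loads and round-trips through CSV", {
  coh <- tiny_cohort()
  expect_s3_class(coh, "tumor_cohort")
  expect_equal(nrow(coh$patients), 3)
  expect_equal(coh$timelines$P3$total_volumes[["TP0"]], 28.4)

  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  coh2 <- load_cohort(paths[["lesions"]], paths[["patients"]])
  expect_identical(coh2$lesions$volume_cc, coh$lesions$volume_cc)
  expect_equal(coh2$patients$os_days, coh$patients$os_days)
  expect_equal(coh2$timelines$P1$offsets[["TP-1"]], -100)
})

test_that("schema violations are all reported with their location", {
  les <- tiny_lesions(); les$volume_cc[2] <- 0
  expect_error(load_cohort(les, tiny_patients()), "row 2")

  les <- tiny_lesions(); les$timepoint[1] <- "TP9"
  err <- tryCatch(load_cohort(les, tiny_patients()),
                  error = conditionMessage)
  expect_match(err, "unknown timepoint")
  # dropping P2's TP0 row must name the patient
  les <- tiny_lesions()[-4, ]
  expect_error(load_cohort(les, tiny_patients()), "P2")

  les <- rbind(tiny_lesions(), tiny_lesions()[7, ])
  expect_error(load_cohort(les, tiny_patients()), "duplicate lesion key")

  pats <- tiny_patients(); pats$pfs_days[1] <- 900  # exceeds os_days = 800
  expect_error(load_cohort(tiny_lesions(), pats), "PFS")

  # several violations reported together
  les <- tiny_lesions(); les$volume_cc[2] <- 0; les$timepoint[1] <- "TP9"
  err <- tryCatch(load_cohort(les, tiny_patients()),
                  error = conditionMessage)
  expect_match(err, "non-positive volume")
  expect_match(err, "unknown timepoint")
})

test_that("missing required columns are rejected up front", {
  les <- tiny_lesions(); les$volume_cc <- NULL
  expect_error(load_cohort(les, tiny_patients()), "volume_cc")
})

test_that("lesion aggregation is an exact sum with an absent-timepoint signal", {
  m <- data.frame(timepoint = c("TP0", "TP0"), volume_cc = c(10, 18.4))
  expect_identical(aggregate_lesions(m, "TP0"), 28.4)
  expect_identical(aggregate_lesions(
    data.frame(timepoint = "TP0", volume_cc = 0.4), "TP0"), 0.4)
  expect_identical(aggregate_lesions(
    data.frame(timepoint = rep("TP0", 73), volume_cc = rep(1, 73)), "TP0"),
    73)
  expect_true(is.na(aggregate_lesions(m, "TP-1")))
})

test_that("imputation inserts the conventional pretreatment point once", {
  coh <- tiny_cohort()
  imp <- impute_pretreatment(coh)
  tl <- imp$timelines$P2
  expect_equal(tl$offsets[["TP-1"]], -90)
  expect_equal(tl$total_volumes[["TP-1"]], 0.1)
  expect_true(tl$imputed[["TP-1"]])
  expect_true(tl$imputation_applied)
  # measured patient untouched
  expect_identical(imp$timelines$P1, coh$timelines$P1)
  # idempotence
  imp2 <- impute_pretreatment(imp)
  expect_identical(imp2$timelines, imp$timelines)
  # custom policy
  imp3 <- impute_pretreatment(coh, imputation_policy(0.01, -150))
  expect_equal(imp3$timelines$P2$total_volumes[["TP-1"]], 0.01)
  expect_equal(imp3$timelines$P2$offsets[["TP-1"]], -150)
})

test_that("imputation policy constants are validated", {
  expect_error(imputation_policy(volume = 0), "volume")
  expect_error(imputation_policy(offset = 10), "offset")
})

test_that("an imputation volume above the smallest baseline volume warns", {
  coh <- tiny_cohort()  # smallest TP0 volume is 20
  expect_warning(impute_pretreatment(coh, imputation_policy(25, -90)),
                 "negative")
})

test_that("cohort growth rates use pretreatment data only", {
  coh <- tiny_cohort()
  fits <- compute_cohort_growth_rates(coh)
  expect_equal(nrow(fits), 3)
  expect_equal(fits$alpha[fits$patient_id == "P2"], log(28.4 / 0.1) / 90,
               tolerance = 1e-12)
  expect_equal(fits$alpha[fits$patient_id == "P1"], log(20 / 5) / 100,
               tolerance = 1e-12)
  expect_equal(fits$n_obs, rep(2L, 3))  # TP+1 never enters the fit
  expect_equal(unname(fits$imputed), c(FALSE, TRUE, FALSE))
})

test_that("equal pre and baseline volumes give alpha zero", {
  les <- tiny_lesions(); les$volume_cc[les$patient_id == "P1"] <- 20
  fits <- compute_cohort_growth_rates(load_cohort(les, tiny_patients()))
  expect_identical(fits$alpha[fits$patient_id == "P1"], 0)
})

test_that("smaller imputed volumes and shorter intervals increase alpha", {
  coh <- tiny_cohort()
  a <- function(vol, off) {
    f <- compute_cohort_growth_rates(coh, policy = imputation_policy(vol, off))
    f$alpha[f$patient_id == "P2"]
  }
  expect_gt(a(0.01, -90), a(0.1, -90))
  expect_gt(a(0.1, -90), a(1, -90))
  expect_gt(a(0.1, -30), a(0.1, -90))
  expect_gt(a(0.1, -90), a(0.1, -150))
})

test_that("an out-of-range measured interval warns but is admitted", {
  pats <- tiny_patients(); pats$tp_minus1_offset_days[1] <- -400
  expect_warning(load_cohort(tiny_lesions(), pats), "range")
})
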