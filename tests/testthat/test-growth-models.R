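test_that("model registry defines seven laws with the right parameter counts", {
  nms <- growth_models()
  expect_length(nms, 7)
  expect_equal(nms[1], "exponential")
  for (nm in nms) {
    spec <- growth_model_spec(nm)
    if (nm == "exponential") expect_length(spec$param_names, 1)
    else expect_gte(length(spec$param_names), 2)
    # rhs finite at the smallest volume on the fitting domain
    p <- spec$init(data.frame(t = c(0, 30), v = c(1, 2)))
    names(p) <- spec$param_names
    expect_true(is.finite(spec$rhs(1e-3, p)), info = nm)
  }
  expect_error(growth_model_spec("verhulst"))
})

test_that("two-point exponential fit matches the closed form", {
  f <- fit_exponential_two_point(0.1, 28.4, 90)
  expect_equal(f$alpha, log(28.4 / 0.1) / 90, tolerance = 1e-12)
  expect_equal(round(f$alpha, 5), 0.06277)
  expect_true(f$converged)
  expect_identical(f$rss, 0)
  expect_false(f$underdetermined)

  expect_identical(fit_exponential_two_point(5, 5, 90)$alpha, 0)
  expect_equal(fit_exponential_two_point(10, 5, 90)$alpha, log(0.5) / 90,
               tolerance = 1e-12)
})

test_that("invalid two-point inputs name the offending field", {
  expect_error(fit_exponential_two_point(0, 28.4, 90), "v_pre")
  expect_error(fit_exponential_two_point(0.1, -1, 90), "v_base")
  expect_error(fit_exponential_two_point(0.1, 28.4, 0), "dt")
})

test_that("ODE solver reproduces closed forms", {
  expect_equal(solve_growth_ode("exponential", c(a = 0.01), 1, c(0, 100)),
               c(1, exp(1)), tolerance = 1e-6)
  expect_equal(solve_growth_ode("exponential", c(a = 0), 7.3,
                                c(0, 13, 55, 200)),
               rep(7.3, 4), tolerance = 1e-10)
  # anchored at the first grid point, whatever its time value
  v <- solve_growth_ode("exponential", c(a = 0.02), 4, c(-50, 0, 50))
  expect_equal(v, 4 * exp(0.02 * (c(-50, 0, 50) + 50)), tolerance = 1e-6)
  expect_error(solve_growth_ode("exponential", c(a = 0.01), -1, c(0, 10)),
               "v0")
  expect_error(solve_growth_ode("exponential", c(a = 0.01), 1, c(10, 0)),
               "increasing")
})

test_that("capacity-limited laws approach the exponential limit", {
  # logistic: dV/dt = aV(1 - V/b) -> aV directly as b -> infinity
  v <- solve_growth_ode("logistic", c(a = 0.05, b = 1e6), 1, c(0, 90))
  expect_equal(v[2], exp(0.05 * 90), tolerance = 1e-2)
  # gompertz: for V << b the rate a*log(b/V) is nearly constant, so the
  # solution is exponential with effective rate a*log(b/V0)
  a <- 2e-4; b <- 1e5
  v <- solve_growth_ode("gompertz", c(a = a, b = b), 1, c(0, 90))
  expect_equal(v[2], exp(a * log(b) * 90), tolerance = 1e-2)
})

test_that("general fit agrees with the closed form for two exponential points", {
  obs <- data.frame(t = c(-90, 0), v = c(0.1, 28.4))
  f <- fit_growth_model("exponential", obs)
  expect_equal(f$alpha, log(28.4 / 0.1) / 90, tolerance = 1e-6)
  expect_false(f$underdetermined)
  # the optimizer route (log-scale objective) reaches the same optimum
  f2 <- fit_growth_model("exponential", obs, log_scale = TRUE)
  expect_equal(f2$alpha, f$alpha, tolerance = 1e-6)
})

test_that("a single observation is rejected", {
  expect_error(fit_growth_model("exponential", data.frame(t = 0, v = 5)),
               "two")
  expect_error(fit_growth_model("gompertz", data.frame(t = 0, v = 5)))
})

test_that("parameters are recovered from noise-free trajectories", {
  cases <- list(
    exponential = list(p = c(a = 0.02), v0 = 5),
    mendelsohn = list(p = c(a = 0.05, b = 0.8), v0 = 5),
    logistic = list(p = c(a = 0.05, b = 500), v0 = 10),
    linear = list(p = c(a = 2, b = 50), v0 = 10),
    surface = list(p = c(a = 3, b = 50), v0 = 10),
    gompertz = list(p = c(a = 0.05, b = 300), v0 = 10),
    bertalanffy = list(p = c(a = 0.5, b = 0.1), v0 = 8))
  t_grid <- c(0, 30, 60, 90, 120, 150)
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    v <- solve_growth_ode(nm, cs$p, cs$v0, t_grid)
    f <- fit_growth_model(nm, data.frame(t = t_grid, v = v))
    expect_true(f$converged, info = nm)
    expect_false(f$underdetermined, info = nm)
    expect_equal(unname(coef(f)), unname(cs$p), tolerance = 1e-4,
                 info = nm)
  }
})

test_that("two-parameter fits to two points are flagged underdetermined", {
  obs <- data.frame(t = c(-90, 0), v = c(0.1, 28.4))
  f <- fit_growth_model("gompertz", obs)
  expect_true(f$underdetermined)
  expect_lt(f$rss, 1e-4)  # two points still interpolated
})

test_that("exponential alpha is scale invariant and signed by volume change", {
  set.seed(11)
  for (i in 1:25) {
    v1 <- runif(1, 0.01, 1e4); v2 <- runif(1, 0.01, 1e4)
    dt <- runif(1, 6, 363); c0 <- runif(1, 0.1, 100)
    a1 <- fit_exponential_two_point(v1, v2, dt)$alpha
    a2 <- fit_exponential_two_point(c0 * v1, c0 * v2, dt)$alpha
    expect_equal(a1, a2, tolerance = 1e-10)
    expect_identical(sign(a1), sign(v2 - v1))
  }
})

test_that("alpha decreases in pretreatment volume and in interval length", {
  a <- vapply(c(0.05, 0.5, 5, 20), function(vp)
    fit_exponential_two_point(vp, 28.4, 90)$alpha, numeric(1))
  expect_true(all(diff(a) < 0))
  a <- vapply(c(30, 90, 180, 360), function(dt)
    fit_exponential_two_point(0.1, 28.4, dt)$alpha, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("fit results flatten to a delimited-ready table", {
  fits <- list(P1 = fit_exponential_two_point(0.1, 28.4, 90),
               P2 = fit_exponential_two_point(5, 5, 90))
  tab <- growth_fit_table(fits)
  expect_equal(tab$patient_id, c("P1", "P2"))
  expect_true(all(c("model", "a", "alpha", "rss", "converged",
                    "underdetermined") %in% names(tab)))
  expect_equal(tab$alpha, c(log(284) / 90, 0), tolerance = 1e-12)
})

test_that("predict and residuals are consistent with the fitted curve", {
  obs <- data.frame(t = c(-90, 0), v = c(0.1, 28.4))
  f <- fit_growth_model("exponential", obs)
  expect_equal(predict(f), obs$v, tolerance = 1e-9)
  expect_equal(residuals(f), c(0, 0), tolerance = 1e-9)
  expect_equal(predict(f, 90), 0.1 * exp(f$alpha * 180), tolerance = 1e-6)
})
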