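test_that("parameter and state constructors validate their domains", {
  expect_s3_class(model_parameters(), "sir_parameters")
  expect_error(model_parameters(gamma = -0.2), "gamma")
  expect_error(model_parameters(beta_star = 0), "beta_star")
  expect_error(model_parameters(lambda1 = -0.1), "lambda1")
  expect_error(model_parameters(nu = NA_real_), "nu")
  expect_error(initial_state(S0 = -1, I0 = 1, R0 = 1), "non-negative")
  expect_error(initial_state(D0 = 0), "D0")
  expect_error(initial_state(S0 = 0.5, I0 = 0.1, R0 = 0), "equal N")
})

test_that("society classification follows the distance intervals", {
  expect_identical(classify_society(0.75), "small")
  expect_identical(classify_society(1.05), "medium")
  expect_identical(classify_society(1.35), "large")
  # boundaries: 1 m closes the medium interval from below, 1.2 m from above
  expect_identical(classify_society(c(1, 1.2, 1.2000001)),
                   c("medium", "medium", "large"))
  expect_identical(classify_society(0.9999999), "small")
  expect_error(classify_society(0), "> 0")
  expect_error(classify_society(-1), "> 0")
})

test_that("all rate forms equal beta* at the scaling distance", {
  for (nu in c(0.5, 1, 1.5, 4.5, 10.5)) {
    p <- model_parameters(nu = nu, beta_star = 0.5, D_bar_star = 1.05)
    for (form in rate_forms)
      expect_equal(transmission_rate(1.05, form, p), 0.5, tolerance = 1e-15)
  }
})

test_that("rate forms have the stated limits at D = 0 and at infinity", {
  for (nu in c(0.5, 1, 1.5)) {
    p <- model_parameters(nu = nu, beta_star = 0.5)
    expect_equal(transmission_rate(0, "beta1", p), 2^nu * 0.5)
    expect_equal(transmission_rate(0, "beta2", p), 2 * 0.5)
    expect_equal(transmission_rate(0, "beta4", p), exp(1) * 0.5)
    expect_error(transmission_rate(0, "beta3", p), "unbounded")
  }
  # beta3 grows without bound near 0
  p1 <- model_parameters(nu = 1)
  expect_gt(transmission_rate(1e-8, "beta3", p1), 1e6)
  # all forms vanish far away (nu >= 1)
  for (form in rate_forms)
    expect_lt(transmission_rate(1e6 * 1.05, form, p1), 1e-3 * 0.5)
})

test_that("every rate form is strictly decreasing in D", {
  # capped at 4 m: beyond ~4.6 m beta4 at nu = 4.5 underflows to exactly 0
  grid <- seq(0.05, 4, length.out = 400)
  for (nu in c(0.5, 1, 1.5, 4.5)) {
    p <- model_parameters(nu = nu)
    for (form in rate_forms) {
      b <- transmission_rate(grid, form, p)
      expect_true(all(diff(b) < 0), info = paste(form, "nu =", nu))
    }
  }
})

test_that("rate forms are convex on their convexity domains", {
  # beta1 and beta3 are convex everywhere for every nu; beta2 and beta4
  # are convex everywhere only for nu <= 1 and acquire an inflection
  # point below Dbar* for larger nu (e.g. beta4 at nu = 1.5 is concave
  # below ~0.5 m), so for nu > 1 they are checked from Dbar* outward.
  grid <- seq(0.05, 4, length.out = 400)
  tail_grid <- seq(1.05, 4, length.out = 400)
  for (nu in c(0.5, 1, 1.5, 4.5)) {
    p <- model_parameters(nu = nu)
    for (form in c("beta1", "beta3"))
      expect_true(all(diff(transmission_rate(grid, form, p),
                           differences = 2) > 0),
                  info = paste(form, "nu =", nu))
    for (form in c("beta2", "beta4")) {
      g <- if (nu <= 1) grid else tail_grid
      expect_true(all(diff(transmission_rate(g, form, p),
                           differences = 2) > 0),
                  info = paste(form, "nu =", nu))
    }
  }
})

test_that("the four rates have the documented ordering around Dbar*", {
  p <- model_parameters(nu = 1.5)
  before <- seq(0, 1.05, length.out = 1002)[2:1001]
  b <- sapply(rate_forms, function(f) transmission_rate(before, f, p))
  expect_true(all(b[, "beta2"] < b[, "beta1"]))
  expect_true(all(b[, "beta4"] < b[, "beta3"]))
  # the beta1/beta4 pair swaps below ~0.032 m, where the stated 0+ limits
  # force beta1 above beta4 (2^1.5 > e); the documented ordering is
  # checked from 0.05 m, the smallest epidemiologically meaningful
  # interpersonal distance, up to the scaling distance
  phys <- seq(0.05, 1.05, length.out = 1001)[-1001]
  expect_true(all(transmission_rate(phys, "beta1", p) <
                  transmission_rate(phys, "beta4", p)))
  # and beta1 > beta4 indeed holds just below the crossover
  expect_gt(transmission_rate(0.02, "beta1", p),
            transmission_rate(0.02, "beta4", p))
  after <- seq(1.05, 5, length.out = 1001)[-1]
  a <- sapply(rate_forms, function(f) transmission_rate(after, f, p))
  expect_true(all(a[, "beta4"] < a[, "beta3"]))
  expect_true(all(a[, "beta3"] < a[, "beta2"]))
  expect_true(all(a[, "beta2"] < a[, "beta1"]))
})

test_that("beta1 and beta2 coincide identically at nu = 1", {
  p <- model_parameters(nu = 1)
  grid <- seq(0.01, 10, length.out = 500)
  expect_equal(transmission_rate(grid, "beta1", p),
               transmission_rate(grid, "beta2", p), tolerance = 1e-14)
})

test_that("beta3 steepens with nu below Dbar* and flattens above", {
  nus <- c(0.5, 1, 1.5, 2)
  below <- sapply(nus, function(nu)
    transmission_rate(0.6, "beta3", model_parameters(nu = nu)))
  above <- sapply(nus, function(nu)
    transmission_rate(1.8, "beta3", model_parameters(nu = nu)))
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) < 0))
})

test_that("rate evaluation rejects invalid distances and forms", {
  p <- model_parameters()
  expect_error(transmission_rate(-0.1, "beta1", p), "non-negative")
  expect_error(transmission_rate(1, "beta9", p), "form")
})

test_that("basic reproduction number matches hand-evaluated references", {
  expect_equal(basic_reproduction_number(
    "beta3", model_parameters(nu = 1, D_star = 0.75)), 3.5)
  # any form at D* = Dbar* gives beta*/gamma = 2.5
  for (form in rate_forms)
    expect_equal(basic_reproduction_number(
      form, model_parameters(nu = 2, D_star = 1.05)), 2.5)
  r <- basic_reproduction_number(
    "beta4", model_parameters(nu = 1, D_star = 1.35))
  expect_equal(r, 0.5 * exp(1 - 1.35 / 1.05) / 0.2, tolerance = 1e-12)
  expect_equal(round_half_away(r, 1), 1.9)
})

test_that("half-away rounding breaks ties away from zero", {
  expect_equal(round_half_away(c(2.25, 2.35, -2.25), 1), c(2.3, 2.4, -2.3))
  expect_equal(round_half_away(0.05, 1), 0.1)
})
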