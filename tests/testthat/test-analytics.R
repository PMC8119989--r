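# one long reference run shared across the identity tests
fig6_traj <- simulate_preset("fig6_small", t_end = 2000)

test_that("cumulative Simpson quadrature is fourth-order accurate", {
  h <- 0.1
  x <- seq(0, 10, by = h)
  # exact (to round-off) for quadratics at every grid point
  expect_lt(max(abs(proxsir:::cum_simpson(x^2, h) - x^3 / 3)), 1e-12)
  # h^4 error scale for smooth integrands; trapezoid would give ~8e-4
  expect_lt(max(abs(proxsir:::cum_simpson(sin(x), h) - (1 - cos(x)))), 1e-5)
  # the single asymmetric-rule interval at odd offsets is the only
  # place cubics pick up error (h^4/4 locally)
  expect_lt(max(abs(proxsir:::cum_simpson(x^3, h) - x^4 / 4)), 5e-5)
  expect_equal(proxsir:::cum_simpson(c(1, 1), 0.5), c(0, 0.5))
})

test_that("closed-form distance matches the integrated distance", {
  expect_lt(max(abs(closed_form_distance(fig6_traj) - fig6_traj$D)), 1e-5)
  # t = 0 returns D0 exactly
  expect_equal(closed_form_distance(fig6_traj)[1], 0.75)
  expect_error(closed_form_distance(fig6_traj, t_eval = -1), "span")

  # pure relaxation when I = 0: only the exponential term survives
  p <- model_parameters(D_star = 1.05)
  relax <- simulate_sir(p, initial_state(S0 = 1, I0 = 0, R0 = 0, D0 = 1.8),
                        "beta2", t_end = 100)
  expect_equal(closed_form_distance(relax),
               1.05 + 0.75 * exp(-0.03 * relax$t), tolerance = 1e-9)
})

test_that("the susceptible log-identity holds along solutions", {
  rep6 <- susceptible_identity(fig6_traj)
  expect_lt(rep6$max_residual, 1e-5)
  expect_equal(rep6$residual[1], 0, tolerance = 1e-14)

  # lambda1 = 0: no resistance term; identity reduces to the line integral
  p0 <- model_parameters(lambda1 = 0, D_star = 0.75)
  tr0 <- simulate_sir(p0, initial_state(D0 = 0.75), "beta3", t_end = 300)
  expect_lt(susceptible_identity(tr0)$max_residual, 1e-5)

  # identity is undefined without prevalence feedback
  trc <- simulate_sir(classical_params(), classical_init(), "beta3",
                      t_end = 50)
  expect_error(susceptible_identity(trc), "lambda2")
})

test_that("final-size expression agrees with the long-run susceptibles", {
  fs <- final_susceptibles(fig6_traj)
  expect_lt(abs(fs$value - fs$S_end), 1e-3)
  expect_lt(fs$exponent_tail_bound, 1e-6)

  # power-law special case is numerically equivalent to the generic form
  special <- final_susceptibles_beta3(fig6_traj)
  expect_lt(abs(special - fs$value) / fs$value, 1e-6)

  # preconditions
  short <- simulate_preset("fig6_small", t_end = 30)
  expect_error(final_susceptibles(short), "equilibrium")
  expect_error(final_susceptibles_beta3(simulate_preset("fig5c_small")),
               "nu = 1")
})

test_that("first-peak detection matches the classical SIR closed form", {
  traj <- simulate_sir(classical_params(), classical_init(), "beta1",
                       t_end = 150)
  pk <- find_first_peak(traj)
  expect_true(pk$interior)
  expect_equal(pk$peak_prevalence, sir_peak_prevalence(2.5), tolerance = 1e-3)
  # quadratic refinement stays within a grid cell of the raw argmax
  expect_lt(abs(pk$peak_time - traj$t[which.max(traj$prevalence)]), 0.1)
  # and refines above the grid maximum
  expect_gte(pk$peak_prevalence, max(traj$prevalence) - 1e-12)
})

test_that("subcritical epidemics have no interior peak", {
  p <- classical_params(beta_star = 0.1)   # R0 = 0.5
  traj <- simulate_sir(p, classical_init(), "beta2", t_end = 100)
  pk <- find_first_peak(traj)
  expect_false(pk$interior)
  expect_equal(pk$peak_time, 0)
  expect_identical(nrow(find_all_peaks(traj)), 0L)
})

test_that("peak census: one constant-rate peak, several with feedback", {
  trc <- simulate_sir(classical_params(), classical_init(), "beta4",
                      t_end = 300)
  expect_identical(nrow(find_all_peaks(trc)), 1L)

  osc <- simulate_preset("fig9_nu10.5_beta3")
  pks <- find_all_peaks(osc, min_prominence = 1e-4)
  expect_gte(nrow(pks), 2)
  expect_true(all(diff(pks$peak_time) > 0))
  expect_true(all(pks$prominence >= 1e-4))

  # disease-free: no peaks at all
  quiet <- simulate_sir(model_parameters(),
                        initial_state(S0 = 1, I0 = 0, R0 = 0, D0 = 1.05),
                        "beta1", t_end = 50)
  expect_identical(nrow(find_all_peaks(quiet)), 0L)
})

test_that("prominence threshold filters shallow ripples", {
  osc <- simulate_preset("fig9_nu10.5_beta1")
  all_p <- find_all_peaks(osc, min_prominence = 0)
  main <- find_all_peaks(osc, min_prominence = 0.01)
  expect_gte(nrow(all_p), nrow(main))
  expect_gte(nrow(main), 1)
})
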