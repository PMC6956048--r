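test_that("engineering stress and strain follow their definitions", {
  rec <- tensile_record(time_s = 0:4, displacement_mm = seq(0, 0.8, 0.2),
                        load_N = rep(1, 5), strip_width_mm = 5,
                        thickness_mm = 0.4, gauge_length_mm = 8)
  cur <- compute_stress_strain(rec)
  expect_equal(cur$stress_MPa, rep(1 / (5 * 0.4), 5)) # 0.5 MPa
  expect_equal(cur$strain, seq(0, 0.8, 0.2) / 8)
  expect_equal(cur$strain[1], 0)
  # constant displacement -> zero strain throughout
  rec2 <- tensile_record(0:4, rep(0.3, 5), 1:5, 5, 0.4, 8)
  expect_true(all(compute_stress_strain(rec2)$strain == 0))
})

test_that("a noise-free linear record returns its modulus exactly", {
  rec <- generate_tensile_record(tensile_params(model = "linear",
                                                E_linear = 5,
                                                noise_sd_N = 0))
  cur <- compute_stress_strain(rec)
  for (win in list(c(0, 1), c(0.7, 0.9), c(0.2, 0.5))) {
    est <- estimate_modulus(cur, win[1], win[2])
    expect_equal(est$young_modulus_MPa, 5, tolerance = 1e-9)
    expect_equal(est$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("the toe-exponential tangent matches the closed-form derivative", {
  p <- tensile_params(model = "toe-exponential", toe_amplitude = 0.5,
                      toe_rate = 8, max_strain = 0.3, n_points = 2000,
                      noise_sd_N = 0)
  cur <- compute_stress_strain(generate_tensile_record(p))
  # finite-difference tangent of the recorded curve vs analytic law
  mid <- 1000
  fd <- (cur$stress_MPa[mid + 1] - cur$stress_MPa[mid - 1]) /
    (cur$strain[mid + 1] - cur$strain[mid - 1])
  analytic <- 0.5 * 8 * exp(8 * cur$strain[mid])
  expect_equal(fd, analytic, tolerance = 1e-4)
  # OLS slope over [0.7, 0.9] x max strain ~ mean analytic tangent there
  est <- estimate_modulus(cur, 0.7, 0.9)
  lo <- 0.7 * 0.3; hi <- 0.9 * 0.3
  mean_tangent <- (0.5 * (exp(8 * hi) - exp(8 * lo))) / (hi - lo)
  expect_lt(abs(est$young_modulus_MPa - mean_tangent) / mean_tangent, 0.02)
})

test_that("the displacement rate equals the default 0.1 mm/s everywhere", {
  rec <- generate_tensile_record(tensile_params(noise_sd_N = 0))
  rate <- diff(rec$displacement_mm) / diff(rec$time_s)
  expect_equal(rate, rep(0.1, length(rate)), tolerance = 1e-12)
})

test_that("modulus estimation is deterministic and scale-consistent", {
  p <- tensile_params(noise_sd_N = 0.005, seed = 13)
  cur <- compute_stress_strain(generate_tensile_record(p))
  e1 <- estimate_modulus(cur); e2 <- estimate_modulus(cur)
  expect_identical(e1, e2)
  # doubling load and cross-section leaves stress, hence E, unchanged
  rec <- generate_tensile_record(p)
  rec2 <- tensile_record(rec$time_s, rec$displacement_mm, 2 * rec$load_N,
                         attr(rec, "strip_width_mm"),
                         2 * attr(rec, "thickness_mm"),
                         attr(rec, "gauge_length_mm"))
  expect_equal(estimate_modulus(compute_stress_strain(rec2))$young_modulus_MPa,
               e1$young_modulus_MPa, tolerance = 1e-12)
})

test_that("degenerate records and windows are rejected", {
  expect_error(tensile_record(0:4, 1:5, 1:5, strip_width_mm = 0,
                              thickness_mm = 0.4, gauge_length_mm = 8),
               "positive")
  expect_error(tensile_record(c(0, 0, 1), 1:3, 1:3, 5, 0.4, 8),
               "increasing")
  cur <- compute_stress_strain(generate_tensile_record(
    tensile_params(n_points = 50, noise_sd_N = 0)))
  expect_error(estimate_modulus(cur, 0.5, 0.501), "need >= 2")
})
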