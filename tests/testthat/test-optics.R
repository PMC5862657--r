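# Scalar transfer-function mathematics: wavelength, aberration phase and the
# complex/real transfer functions.
#
# Frozen oracle values in this file were computed independently (CODATA
# constants, direct evaluation of the closed forms in a separate
# environment) before being asserted here.

test_that("relativistic electron wavelength matches independent evaluation", {
  expect_equal(electron_wavelength(300), 0.0196875, tolerance = 1e-5)
  expect_equal(electron_wavelength(200), 0.0250793, tolerance = 1e-5)
  expect_equal(electron_wavelength(100), 0.0370144, tolerance = 1e-5)
  # customary rounded values
  expect_equal(signif(electron_wavelength(300), 2), 0.02)
  expect_equal(round(electron_wavelength(100), 3), 0.037)
  # monotone decreasing with energy
  expect_true(electron_wavelength(300) < electron_wavelength(100))
  lams <- electron_wavelength(c(80, 100, 200, 300, 400))
  expect_true(all(diff(lams) < 0))
  expect_error(electron_wavelength(0), "positive")
  expect_error(electron_wavelength(-100), "positive")
})

test_that("optical_model validates and defaults sensibly", {
  m <- optical_model(voltage_kev = 300, defocus = 11000)
  expect_s3_class(m, "optical_model")
  expect_equal(m$amp_contrast, 0.04)
  expect_equal(optical_model(voltage_kev = 100)$amp_contrast, 0.07)
  # wavelength alone is enough
  m2 <- optical_model(wavelength = 0.02, defocus = 1)
  expect_equal(m2$wavelength, 0.02)
  # voltage and wavelength must agree within 1%
  expect_error(optical_model(voltage_kev = 300, wavelength = 0.037),
               "inconsistent")
  expect_silent(optical_model(voltage_kev = 300, wavelength = 0.0197))
  expect_error(optical_model(wavelength = -1), "positive")
  expect_error(optical_model(voltage_kev = 300, amp_contrast = 1), "0, 1")
  expect_error(optical_model(), "voltage_kev or wavelength")
})

test_that("chi reproduces the frozen worked example and limits", {
  m <- optical_model(wavelength = 0.02, defocus = 11000, cs = 0,
                     amp_contrast = 0)
  # independent one-line evaluation: -pi * dF * lambda / d^2 at d = 3.8
  expect_equal(chi(1 / 3.8, m), -47.863600, tolerance = 1e-6)
  expect_equal(chi(0, m), 0)
  # extra phase is a constant offset
  m_pp <- optical_model(wavelength = 0.02, defocus = 11000, amp_contrast = 0,
                        extra_phase = 0.3)
  expect_equal(chi(0, m_pp), 0.3)
  expect_equal(chi(1 / 3.8, m_pp) - chi(1 / 3.8, m), 0.3)
  # defocus and spherical terms cancel at theta^2 = 2 dF / Cs
  mc <- optical_model(wavelength = 0.02, defocus = 11000, cs = 2e7,
                      amp_contrast = 0)
  theta <- sqrt(2 * mc$defocus / mc$cs)
  expect_equal(chi(theta / mc$wavelength, mc), 0, tolerance = 1e-9)
  expect_error(chi(-0.1, m), ">= 0")
})

test_that("astigmatism enters as azimuth-dependent effective defocus", {
  ma <- optical_model(wavelength = 0.02, defocus = 10000, amp_contrast = 0,
                      astig_amount = 2000, astig_angle = 0.4)
  s <- 0.2
  az <- seq(0, 2 * pi, length.out = 25)
  # two-fold symmetry
  expect_equal(chi(s, ma, az), chi(s, ma, az + pi), tolerance = 1e-12)
  # extremes at the astigmatism axis and perpendicular to it
  m_hi <- optical_model(wavelength = 0.02, defocus = 11000, amp_contrast = 0)
  m_lo <- optical_model(wavelength = 0.02, defocus = 9000, amp_contrast = 0)
  expect_equal(chi(s, ma, 0.4), chi(s, m_hi), tolerance = 1e-12)
  expect_equal(chi(s, ma, 0.4 + pi / 2), chi(s, m_lo), tolerance = 1e-12)
})

test_that("complex transfer values have unit modulus and are conjugate", {
  m <- optical_model(wavelength = 0.02, defocus = 11000, amp_contrast = 0.07)
  set.seed(42)
  cv <- stats::runif(1000, -60, 60)
  expect_lt(max(abs(Mod(ctf_p(cv, m)) - 1)), 1e-12)
  expect_lt(max(abs(Mod(ctf_q(cv, m)) - 1)), 1e-12)
  expect_lt(max(Mod(ctf_q(cv, m) - Conj(ctf_p(cv, m)))), 1e-12)
})

test_that("sum identity ctf_p + ctf_q = ctf_r holds to machine precision", {
  set.seed(43)
  cv <- c(seq(-60, 60, length.out = 4001), stats::runif(1000, -60, 60))
  for (w in c(0, 0.04, 0.07, 0.3)) {
    m <- optical_model(wavelength = 0.02, defocus = 11000, amp_contrast = w)
    expect_lt(max(Mod(ctf_p(cv, m) + ctf_q(cv, m) - ctf_r(cv, m))), 1e-12)
  }
})

test_that("real transfer reduces to -2 sin chi and has sine zeros", {
  m0 <- optical_model(wavelength = 0.02, defocus = 11000, amp_contrast = 0)
  cv <- seq(-20, 20, length.out = 801)
  expect_equal(ctf_r(cv, m0), -2 * sin(cv), tolerance = 1e-12)
  expect_equal(ctf_r(-pi / 2, m0), 2)
  expect_lt(max(abs(ctf_r((-3):3 * pi, m0))), 1e-12)
})

test_that("amplitude-contrast phase offset is about 94 degrees at W = 0.07", {
  expect_equal(amp_phase_offset(0.07), 94.01399, tolerance = 1e-6)
  expect_equal(round(amp_phase_offset(0.07)), 94)
  expect_equal(amp_phase_offset(0), 90)
  expect_equal(amp_phase_offset(0.07, "rad"), pi / 2 + asin(0.07))
  expect_error(amp_phase_offset(1), "0, 1")
})
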