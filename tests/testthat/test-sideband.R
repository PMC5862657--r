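# Half-plane complex CTF application, sector plans, soft masking and
# sideband-sample extraction.

.m_fig <- function(w = 0) optical_model(wavelength = 0.02, defocus = 11000,
                                        amp_contrast = w)
.m_scaled <- function(df = 140) optical_model(wavelength = 0.25, defocus = df,
                                              amp_contrast = 0)

test_that("sector_plan builds the rotated boundary set", {
  p8 <- sector_plan(8)
  expect_equal(p8$angles, c(0, 1, 2, 3) * pi / 4)
  expect_equal(p8$n_sectors, 8)
  expect_equal(sector_plan(4)$angles, c(0, pi / 2))
  expect_equal(sector_plan(angles = 0.3)$n_sectors, 2)
  expect_error(sector_plan(5), "2, 4, 6, 8")
})

test_that("applying P then Q with the same boundary is the identity", {
  set.seed(21)
  n <- 64
  ft <- fft2(matrix(stats::rnorm(n * n), n, n))
  m <- .m_fig()
  for (ang in c(0, 0.3, pi / 4)) {
    pq <- apply_complex_ctf(apply_complex_ctf(ft, m, 1, ang, "P"),
                            m, 1, ang, "Q", check = FALSE)
    expect_lt(max(Mod(pq - ft)) / max(Mod(ft)), 1e-14)
  }
})

test_that("P-corrected plus Q-corrected equals the CTFR correction", {
  set.seed(22)
  n <- 64
  ft <- fft2(matrix(stats::rnorm(n * n), n, n))
  sc <- self_conjugate_mask(n)
  for (w in c(0, 0.07)) {
    m <- .m_fig(w)
    psum <- apply_complex_ctf(ft, m, 1, 0.3, "P") +
      apply_complex_ctf(ft, m, 1, 0.3, "Q", check = FALSE)
    rr <- apply_ctfr(ft, m, 1, "sum", check = FALSE)
    expect_lt(max(Mod((psum - rr)[!sc])) / max(Mod(ft)), 1e-13)
    # the untouched self-conjugate frequencies pass through doubled
    expect_equal(psum[sc], 2 * ft[sc], tolerance = 1e-12)
  }
  m <- .m_fig()
  expect_equal(apply_ctfr(ft, m, 1, "half", check = FALSE),
               apply_ctfr(ft, m, 1, "sum", check = FALSE) / 2)
})

test_that("corrected transforms stay Hermitian so images stay real", {
  set.seed(23)
  n <- 64
  img <- matrix(stats::rnorm(n * n), n, n)
  ft <- fft2(img)
  m <- .m_fig(0.07)
  for (side in c("P", "Q")) {
    ftc <- apply_complex_ctf(ft, m, 1, 0.7, side)
    expect_lt(hermitian_residual(ftc), 1e-12)
    back <- ifft2(ftc)
    expect_lt(max(abs(Im(back))) / sqrt(mean(Re(back)^2)), 1e-9)
  }
  # DC untouched; boundary-axis tie-break: +x ray gets CTFP under side P
  ftc <- apply_complex_ctf(ft, m, 1, 0, "P")
  expect_equal(ftc[1, 1], ft[1, 1])
  chiv <- chi(5 / (n * 1), m)
  expect_equal(ftc[6, 1], ft[6, 1] * ctf_p(chiv, m), tolerance = 1e-12)
  expect_equal(ftc[1, 6], ft[1, 6] * ctf_p(chi(5 / n, m), m),
               tolerance = 1e-12)  # +y is on the positive side of the x-axis
  # non-Hermitian input is rejected
  bad <- ft
  bad[3, 5] <- bad[3, 5] + 100
  expect_error(apply_complex_ctf(bad, m, 1), "Hermitian")
})

test_that("soft mask window behaves and matches a quadrature oracle", {
  n <- 128
  ones <- matrix(1, n, n)
  hard <- soft_mask(ones, 1, diameter = 40, edge_width = 0)
  expect_true(all(hard %in% c(0, 1)))
  # idempotent on the plateau (and everywhere for the window itself)
  soft <- soft_mask(ones, 1, diameter = 40, edge_width = 8)
  expect_equal(soft_mask(soft, 1, 40, 0)[hard == 1], soft[hard == 1])
  expect_true(all(soft >= 0 & soft <= 1))
  # total flux against numeric integration of the radial window
  flux <- sum(soft)
  oracle <- pi * 20^2 +
    stats::integrate(function(r) 2 * pi * r * 0.5 * (1 + cos(pi * (r - 20) / 8)),
                     20, 28)$value
  expect_lt(abs(flux - oracle) / oracle, 1e-3)
  expect_error(soft_mask(ones, 1, diameter = 120, edge_width = 8), "exceeds")
  expect_error(soft_mask(ones, 1, diameter = -1), "bad mask")
})

test_that("sideband_correct returns signed zstar planes and zero for zero", {
  n <- 64
  m <- .m_scaled()
  smp0 <- sideband_correct(matrix(0, n, n), m, 1, 24)
  expect_equal(max(smp0$P$amp), 0)
  expect_equal(max(smp0$Q$amp), 0)

  set.seed(24)
  img <- matrix(stats::rnorm(n * n), n, n)
  smp <- sideband_correct(img, m, 1, 24)
  expect_s3_class(smp, "sideband_samples")
  # opposite signed offsets on the two sides, magnitude lambda s^2 / 2
  expect_equal(smp$P$zstar, -smp$Q$zstar)
  g <- freq_grid2(n)
  dz <- m$wavelength * (g$kx^2 + g$ky^2) / n^2 / 2
  nz <- smp$P$zstar != 0
  expect_equal(abs(smp$P$zstar)[nz], dz[nz], tolerance = 1e-12)
  expect_equal(smp$P$zstar[1, 1], 0)
  expect_equal(smp$P$amp, Mod(smp$P$values))
  # warns when the defocus cannot separate the sidebands at Nyquist
  m_low <- .m_scaled(df = 20)
  expect_warning(sideband_correct(img, m_low, 1, 24),
                 "below the full-separation threshold")
  expect_silent(sideband_correct(img, m_low, 1, 24, warn_overlap = FALSE))
})

test_that("recovery is uniform across sector boundaries", {
  # a single-frequency component 1 degree from a boundary axis must be
  # recovered with the same amplitude (within 1%) as one at a sector centre
  n <- 64
  m <- .m_scaled()
  g <- freq_grid2(n)
  smag <- sqrt(g$kx^2 + g$ky^2) / n
  ann <- smag > 0.36 & smag < 0.44
  x <- seq_len(n) - (n / 2 + 1)
  xm <- matrix(x, n, n)
  ym <- matrix(x, n, n, byrow = TRUE)
  disc <- (xm^2 + ym^2) <= 12^2
  ratio_at <- function(az) {
    img <- single_component_image(m, n, 1, particle_diameter = 24,
                                  fringe_resolution = 2.5,
                                  fringe_azimuth = az, amplitude = 1,
                                  shadow_depth = 0)
    smp <- sideband_correct(img, m, 1, 24)
    ideal <- disc * cos(2 * pi * (xm * cos(az) + ym * sin(az)) / 2.5)
    ideal_m <- soft_mask(ideal, 1, 1.2 * 24, 2.4)
    sqrt(sum(smp$P$amp[ann]^2) / sum(Mod(fft2(ideal_m))[ann]^2))
  }
  r_centre <- ratio_at(pi / 2 + pi / 8)        # deep inside a sector
  for (az in c(pi / 2, pi / 2 + pi / 180, pi / 4 - pi / 180)) {
    expect_equal(ratio_at(az) / r_centre, 1, tolerance = 0.01)
  }
})

test_that("fringe centroid finds the delocalised sideband", {
  n <- 64
  m <- .m_scaled()
  img <- single_component_image(m, n, 1, particle_diameter = 24,
                                fringe_resolution = 2.5, shadow_depth = 0)
  disp <- attr(img, "displacement")
  expect_equal(disp, 140 * 0.25 / 2.5)
  cen <- fringe_power_centroid(img, 1, 2.5, window_radius = 12)
  expect_equal(cen$displacement, disp, tolerance = 1.5 / disp)
  expect_error(fringe_power_centroid(matrix(0, n, n), 1, 2.5), "no power")
  # windowed RMS of a constant image is that constant
  expect_equal(windowed_rms(matrix(3, n, n), 1, c(0, 0), 10), 3)
  expect_error(windowed_rms(matrix(3, n, n), 1, c(500, 0), 4), "outside")
})

test_that("flat-sphere degeneracy: P and Q samples agree when curvature is off", {
  # delta-spike phantom whose 3D transform is known analytically; with the
  # curvature forced off both extractions estimate the central section
  set.seed(11)
  n <- 64
  vol <- array(0, c(n, n, n))
  pts <- matrix(0, 6, 3)
  for (j in 1:6) {
    repeat {
      p <- sample(seq(-9, 9), 3, replace = TRUE)
      if (sqrt(sum(p^2)) <= 10) break
    }
    pts[j, ] <- p
    vol[33 + p[1], 33 + p[2], 33 + p[3]] <-
      vol[33 + p[1], 33 + p[2], 33 + p[3]] + 1
  }
  pft <- prepare_volume_ft(vol, 1, oversample = 2)
  m <- .m_scaled(df = 150)
  g <- freq_grid2(n)
  sx <- g$kx / n
  sy <- g$ky / n
  smag <- sqrt(sx^2 + sy^2)
  f0 <- matrix(0i, n, n)
  for (j in 1:6) f0 <- f0 + exp(-2i * pi * (sx * pts[j, 1] + sy * pts[j, 2]))
  img0 <- forward_image(pft, diag(3), m, curvature = "off")
  smp <- sideband_correct(img0, m, 1, 24)
  band <- smag > 0.2 & smag < 0.45 & !self_conjugate_mask(n) &
    sideband_separation(150, 0.25, 1 / pmax(smag, 1e-9)) > 28.8 &
    Mod(f0) > 1
  ctr_ref <- c(1 - n / 2, 1 - n / 2)
  vp <- phase_center2(smp$P$values, ctr_ref)
  vq <- phase_center2(smp$Q$values, ctr_ref)
  expect_gt(sum(band), 100)
  expect_lt(median(Mod(vp[band] - f0[band]) / Mod(f0[band])), 0.15)
  expect_lt(median(Mod(vq[band] - f0[band]) / Mod(f0[band])), 0.15)
  expect_lt(median(Mod(vp[band] - vq[band]) / Mod(vp[band])), 0.15)
})
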