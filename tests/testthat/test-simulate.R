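# Synthetic data: single-component fringe images, chiral phantoms, the
# curved-sphere forward model, rotations and noise.

test_that("single_component_image validates and degenerates correctly", {
  m <- optical_model(wavelength = 0.25, defocus = 140, amp_contrast = 0)
  img <- single_component_image(m, 64, 1, particle_diameter = 24,
                                fringe_resolution = 2.5)
  expect_equal(dim(img), c(64, 64))
  expect_true(all(is.finite(img)))
  expect_lt(hermitian_residual(fft2(img)), 1e-10)
  expect_equal(attr(img, "displacement"), 140 * 0.25 / 2.5)
  # amplitude 0 leaves only the shadow disc
  sh <- single_component_image(m, 64, 1, particle_diameter = 24,
                               fringe_resolution = 2.5, amplitude = 0,
                               shadow_depth = 0.5)
  x <- seq_len(64) - 33
  disc <- outer(x^2, x^2, `+`) <= 12^2
  expect_equal(unclass(sh), -0.5 * disc, ignore_attr = TRUE)
  expect_error(single_component_image(m, 64, 1, fringe_resolution = 1.5),
               "Nyquist")
  big <- optical_model(wavelength = 0.25, defocus = 5000, amp_contrast = 0)
  expect_error(single_component_image(big, 64, 1, particle_diameter = 24,
                                      fringe_resolution = 2.5),
               "cannot contain")
})

test_that("chiral phantom is nonnegative, chiral and reproducible", {
  ph <- make_chiral_phantom(48, 1, 20, seed = 4)
  expect_true(all(ph >= 0))
  expect_lt(attr(ph, "mirror_correlation"), 0.9)
  expect_equal(attr(ph, "mirror_correlation"),
               stats::cor(as.vector(ph), as.vector(mirror_volume(ph))))
  ph2 <- make_chiral_phantom(48, 1, 20, seed = 4)
  expect_identical(unclass(ph), unclass(ph2))
  ph3 <- make_chiral_phantom(48, 1, 20, seed = 5)
  expect_false(identical(unclass(ph), unclass(ph3)))
  expect_error(make_chiral_phantom(16, 1, 20), "fit inside")
  # mirroring twice is the identity
  expect_equal(mirror_volume(mirror_volume(ph)), ph)
})

test_that("Euler conversions and random rotations are proper", {
  set.seed(31)
  rots <- random_rotations(20, seed = 8)
  for (r in rots) {
    expect_equal(det(r), 1, tolerance = 1e-12)
    expect_equal(crossprod(r), diag(3), tolerance = 1e-12)
    e <- matrix_to_euler(r)
    expect_equal(euler_to_matrix(e[1], e[2], e[3]), r, tolerance = 1e-9)
  }
  expect_identical(random_rotations(3, seed = 8)[[2]], rots[[2]])
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
})

test_that("add_noise is seeded, unbiased and optional", {
  img <- matrix(0, 50, 50)
  expect_identical(add_noise(img, 0, 1), img)
  n1 <- add_noise(img, 2, seed = 3)
  expect_identical(n1, add_noise(img, 2, seed = 3))
  expect_false(identical(n1, add_noise(img, 2, seed = 4)))
  # sample sd within 3 SE of the requested sd
  se <- 2 / sqrt(2 * (2500 - 1))
  expect_lt(abs(stats::sd(n1) - 2), 3 * se)
  expect_error(add_noise(img, -1), ">= 0")
})

test_that("forward model is real, linear and rejects improper rotations", {
  ph <- make_chiral_phantom(32, 1, 12, seed = 6)
  pft <- prepare_volume_ft(ph, 1)
  m <- optical_model(wavelength = 0.25, defocus = 70, amp_contrast = 0)
  r <- random_rotations(1, seed = 9)[[1]]
  img <- forward_image(pft, r, m)
  expect_true(all(is.finite(img)))
  expect_lt(hermitian_residual(fft2(img)), 1e-10)
  # linear in the phantom
  img2 <- forward_image(prepare_volume_ft(2 * ph, 1), r, m)
  expect_equal(img2, 2 * img, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(forward_image(pft, diag(c(1, 1, -1)), m), "proper")
  expect_error(forward_image(pft, matrix(0.5, 3, 3), m), "proper")
  # inverted curvature gives a genuinely different image
  expect_gt(max(abs(img - forward_image(pft, r, m, curvature = "inverted"))),
            1e-8)
})

test_that("sideband extraction recovers the 3D transform at +zstar", {
  # phantom of delta spikes, so the 3D transform is known in closed form;
  # this freezes the package's curvature-direction convention: the P-side
  # samples must match F at +zstar and must NOT match F at -zstar
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
  m <- optical_model(wavelength = 0.25, defocus = 150, amp_contrast = 0)
  img <- forward_image(pft, diag(3), m)
  smp <- sideband_correct(img, m, 1, 24)
  g <- freq_grid2(n)
  sx <- g$kx / n
  sy <- g$ky / n
  smag <- sqrt(sx^2 + sy^2)
  aF <- function(z) {
    out <- matrix(0i, n, n)
    for (j in 1:6)
      out <- out +
        exp(-2i * pi * (sx * pts[j, 1] + sy * pts[j, 2] + z * pts[j, 3]))
    out
  }
  tru_p <- aF(smp$P$zstar)
  tru_m <- aF(-smp$P$zstar)
  band <- smag > 0.2 & smag < 0.45 & !self_conjugate_mask(n) &
    sideband_separation(150, 0.25, 1 / pmax(smag, 1e-9)) > 28.8 &
    Mod(tru_p) > 1
  expect_gt(sum(band), 100)
  vals <- phase_center2(smp$P$values, c(1 - n / 2, 1 - n / 2))
  err_p <- median(Mod(vals[band] - tru_p[band]) / Mod(tru_p[band]))
  err_m <- median(Mod(vals[band] - tru_m[band]) / Mod(tru_m[band]))
  expect_lt(err_p, 0.1)                          # interpolation-limited
  expect_lt(median(abs(Arg(vals[band] / tru_p[band]))), 5 * pi / 180)
  expect_gt(err_m, 5 * err_p)                    # wrong sign clearly worse
})

test_that("simulate_dataset is reproducible and well-formed", {
  ds <- simulate_dataset(n_particles = 4, seed = 2, size = 32, diameter = 12,
                         defocus_range = c(60, 80))
  expect_equal(dim(ds$images), c(32, 32, 4))
  expect_true(all(is.finite(ds$images)))
  expect_equal(nrow(ds$particles), 4)
  expect_true(all(ds$particles$defocus_A >= 60 & ds$particles$defocus_A <= 80))
  ds2 <- simulate_dataset(n_particles = 4, seed = 2, size = 32, diameter = 12,
                          defocus_range = c(60, 80))
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$particles, ds2$particles)
  # the table round trips into models/rotations consistent with the truth
  models <- particle_models(ds$particles)
  expect_equal(models[[3]]$defocus, ds$particles$defocus_A[3])
  rots <- particle_rotations(ds$particles)
  expect_equal(rots[[2]], ds$rotations[[2]], tolerance = 1e-9)
})
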