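# Weak-phase image simulator: single-component fringe phantoms, chiral 3D
# phantoms, and a curved-Ewald forward imaging model that makes every
# downstream stage testable without external data.

#' Single-component sideband test image
#'
#' Noise-free weak-phase image of a particle that diffracts only one Fourier
#' component: a uniformly dark disc (the low-frequency shadow of the
#' particle) plus one cosine fringe of spacing `fringe_resolution` confined
#' to the particle disc and propagated through the real transfer function
#' CTFR = CTFP + CTFQ. The defocus chirp delocalises the fringe into two
#' sideband patches displaced by \eqn{\pm\Delta F\lambda/d} from the
#' particle centre, carrying exactly the phase structure the single-sideband
#' correction undoes.
#'
#' @param model an [optical_model] (its defocus sets the delocalisation).
#' @param image_size grid side in pixels (even).
#' @param pixel_size pixel size in Angstrom.
#' @param particle_diameter particle diameter D in Angstrom.
#' @param fringe_resolution fringe spacing d in Angstrom (must satisfy
#'   Nyquist, d >= 2 * pixel_size).
#' @param fringe_azimuth fringe direction in radians.
#' @param amplitude fringe amplitude (arbitrary units).
#' @param shadow_depth depth of the dark shadow disc (same units), default
#'   half the fringe amplitude.
#' @return real `image_size` x `image_size` matrix with attributes
#'   `pixel_size`, `center` (pixels), `displacement` (the per-sideband
#'   in-image displacement \eqn{\Delta F\lambda/d} in Angstrom) and the
#'   generating parameters.
#' @export
single_component_image <- function(model, image_size, pixel_size,
                                   particle_diameter = 80,
                                   fringe_resolution = 3.8,
                                   fringe_azimuth = 0, amplitude = 1,
                                   shadow_depth = amplitude / 2) {
  n <- image_size
  if (n %% 2 != 0) stop("image_size must be even")
  if (fringe_resolution < 2 * pixel_size)
    stop("fringe_resolution violates Nyquist for this pixel size")
  box <- required_box_size(particle_diameter, model$defocus,
                           model$wavelength, fringe_resolution)
  if (box > n * pixel_size)
    stop(sprintf(
      "field %.4g A cannot contain particle plus sidebands (%.4g A needed)",
      n * pixel_size, box))

  center <- c(n / 2 + 1, n / 2 + 1)
  x <- (seq_len(n) - center[1]) * pixel_size
  y <- (seq_len(n) - center[2]) * pixel_size
  xm <- matrix(x, n, n)
  ym <- matrix(y, n, n, byrow = TRUE)
  disc <- (xm^2 + ym^2) <= (particle_diameter / 2)^2

  s0 <- 1 / fringe_resolution
  fringe <- amplitude *
    cos(2 * pi * s0 * (xm * cos(fringe_azimuth) + ym * sin(fringe_azimuth)))
  fringe[!disc] <- 0

  img <- take_real(ifft2(apply_ctfr(fft2(fringe), model, pixel_size,
                                    normalization = "sum", check = FALSE)),
                   what = "simulated fringe image")
  img <- img - shadow_depth * disc
  structure(img, pixel_size = pixel_size, center = center,
            displacement = model$defocus * model$wavelength /
              fringe_resolution,
            particle_diameter = particle_diameter,
            fringe_resolution = fringe_resolution,
            fringe_azimuth = fringe_azimuth, amplitude = amplitude)
}

#' Chiral blob phantom
#'
#' A 3D density with no mirror symmetry: Gaussian blobs arranged on a
#' one-and-a-half-turn helix (plus seeded jitter in radius, width and
#' weight) inside a sphere of the given diameter. Density is nonnegative
#' and the handedness is known by construction (`chirality` attribute), so
#' the phantom gives the curvature-direction validation real discriminating
#' power; its correlation with its own mirror image is stored in the
#' `mirror_correlation` attribute.
#'
#' @param size grid side in voxels (even).
#' @param pixel_size voxel size in Angstrom.
#' @param diameter phantom diameter in Angstrom.
#' @param seed integer seed; the same seed reproduces the same phantom.
#' @param n_blobs number of blobs on the helix.
#' @return real `size^3` array with attributes `pixel_size`, `diameter`,
#'   `chirality` and `mirror_correlation`.
#' @export
make_chiral_phantom <- function(size = 64, pixel_size = 1, diameter = 24,
                                seed = 1, n_blobs = 14) {
  n <- size
  if (n %% 2 != 0) stop("size must be even")
  if (diameter >= n * pixel_size) stop("diameter must fit inside the grid")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  tt <- seq(-1, 1, length.out = n_blobs)
  turns <- 1.5
  ang <- turns * pi * tt + stats::rnorm(n_blobs, 0, 0.15)
  rad <- 0.30 * diameter * stats::runif(n_blobs, 0.75, 1.05)
  cz <- 0.32 * diameter * tt + stats::rnorm(n_blobs, 0, 0.02 * diameter)
  cx <- rad * cos(ang)
  cy <- rad * sin(ang)
  sig <- (diameter / 18) * stats::runif(n_blobs, 0.8, 1.4)
  wgt <- stats::runif(n_blobs, 0.7, 1.3)

  cgrid <- (seq_len(n) - (n / 2 + 1)) * pixel_size
  vol <- array(0, c(n, n, n))
  for (b in seq_len(n_blobs)) {
    gx <- exp(-(cgrid - cx[b])^2 / (2 * sig[b]^2))
    gy <- exp(-(cgrid - cy[b])^2 / (2 * sig[b]^2))
    gz <- exp(-(cgrid - cz[b])^2 / (2 * sig[b]^2))
    vol <- vol + wgt[b] * (gx %o% gy %o% gz)
  }
  mc <- stats::cor(as.vector(vol), as.vector(mirror_volume(vol)))
  structure(vol, pixel_size = pixel_size, diameter = diameter,
            chirality = "right-handed helix", mirror_correlation = mc)
}

#' Mirror a volume through the central xy plane
#'
#' Flips the z axis about the grid centre (periodically, so interior
#' structures mirror exactly), inverting the handedness of the density.
#'
#' @param vol real 3D array with even sides.
#' @return the mirrored array (attributes preserved).
#' @export
mirror_volume <- function(vol) {
  n <- dim(vol)[3]
  out <- vol[, , c(1L, n:2L)]
  attributes(out) <- attributes(vol)
  out
}

#' Oversampled centred 3D transform of a phantom
#'
#' Zero-pads the volume by `oversample` about its centre and returns the
#' centred discrete Fourier transform, which the forward model and any
#' off-section sampling interpolate trilinearly. Padding twofold makes
#' trilinear interpolation accurate to a few parts in a thousand over the
#' usable band.
#'
#' @param vol real cubic array (even side), particle centred at
#'   `(n/2+1)^3`.
#' @param pixel_size voxel size in Angstrom (defaults to the volume's
#'   `pixel_size` attribute).
#' @param oversample integer zero-padding factor (>= 1, default 2).
#' @return an object of class `volume_ft`: list with the centred complex
#'   array `values` (DC at `(npad/2+1)^3`), `npad`, `n`, `pixel_size`,
#'   `oversample`.
#' @export
prepare_volume_ft <- function(vol, pixel_size = NULL, oversample = 2) {
  n <- dim(vol)[1]
  if (!all(dim(vol) == n)) stop("volume must be cubic")
  if (is.null(pixel_size)) pixel_size <- attr(vol, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size not given and not an attribute")
  npad <- oversample * n
  vp <- array(0, c(npad, npad, npad))
  lo <- npad / 2 - n / 2 + 1
  hi <- lo + n - 1
  vp[lo:hi, lo:hi, lo:hi] <- vol
  # move the centre voxel to index 1 so phases are referred to the particle
  # centre, then re-centre the spectrum
  values <- fftshift(fft3(fftshift(vp)))
  # the -npad/2 Nyquist planes (centred index 1) have no +npad/2 mirror in
  # storage; zero them so interpolation at +/-s is exactly conjugate and
  # simulated images are real to machine precision
  values[1, , ] <- 0i
  values[, 1, ] <- 0i
  values[, , 1] <- 0i
  structure(list(values = values, npad = npad, n = n,
                 pixel_size = pixel_size, oversample = oversample),
            class = "volume_ft")
}

# vectorised trilinear interpolation in a centred complex 3D array at
# fractional 1-based voxel coordinates (M x 3); corners outside the grid
# contribute 0, so interpolation at exactly opposite coordinates of a
# conjugate-symmetric array stays exactly conjugate even at the band edge
trilinear_gather <- function(arr, coords) {
  n1 <- dim(arr)[1]; n2 <- dim(arr)[2]; n3 <- dim(arr)[3]
  i0 <- floor(coords)
  f <- coords - i0
  acc <- complex(length.out = nrow(coords))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- i0[, 1] + dx; cy <- i0[, 2] + dy; cz <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    valid <- which(cx >= 1 & cx <= n1 & cy >= 1 & cy <= n2 &
                     cz >= 1 & cz <= n3 & w > 0)
    if (!length(valid)) next
    lin <- cx[valid] + (cy[valid] - 1) * n1 + (cz[valid] - 1) * n1 * n2
    acc[valid] <- acc[valid] + w[valid] * arr[lin]
  }
  acc
}

#' Curved-Ewald weak-phase forward image
#'
#' Simulates the bright-field image of a 3D phantom in a given orientation:
#' the image transform at each 2D frequency `s` is
#' \deqn{J(s) = CTFP(s)\,F(R(s, -\Delta z^\ast)) +
#'             CTFQ(s)\,F(R(s, +\Delta z^\ast))}
#' with \eqn{\Delta z^\ast = \lambda|s|^2/2}, `F` the phantom's 3D transform
#' (trilinearly interpolated in its oversampled grid) and `R` the
#' orientation applied to the sampling plane. The two terms are the two
#' pseudo-Friedel-related sidebands; the model is Hermitian by construction,
#' so the image is real. With `curvature = "off"` the offset is forced to
#' zero and the model reduces exactly to CTFR times the central-section
#' projection; `"inverted"` negates it.
#'
#' @param phantom_ft a [prepare_volume_ft()] object (or a raw volume, which
#'   is prepared on the fly).
#' @param rotation 3x3 proper rotation matrix (see [euler_to_matrix()]).
#' @param model an [optical_model].
#' @param curvature `"on"`, `"off"` or `"inverted"`.
#' @param image_size output image side in pixels; default the phantom side.
#' @return real image matrix with attributes `pixel_size` and `center`.
#' @export
forward_image <- function(phantom_ft, rotation, model,
                          curvature = c("on", "off", "inverted"),
                          image_size = NULL) {
  curvature <- match.arg(curvature)
  if (!inherits(phantom_ft, "volume_ft"))
    phantom_ft <- prepare_volume_ft(phantom_ft)
  if (!is.matrix(rotation) || any(dim(rotation) != 3) ||
      abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be a proper 3x3 rotation matrix")
  dir <- switch(curvature, on = 1, off = 0, inverted = -1)

  apix <- phantom_ft$pixel_size
  n <- if (is.null(image_size)) phantom_ft$n else image_size
  g <- freq_grid2(n)
  sx <- as.vector(g$kx) / (n * apix)
  sy <- as.vector(g$ky) / (n * apix)
  smag <- sqrt(sx^2 + sy^2)
  band <- smag < 1 / (2 * apix) & !as.vector(self_conjugate_mask(n))
  band[smag == 0] <- TRUE  # keep DC

  dz <- dir * model$wavelength * smag^2 / 2
  npad <- phantom_ft$npad
  ctr <- npad / 2 + 1
  to_idx <- function(p) t(p) * (npad * apix) + ctr
  pp <- rbind(sx, sy, dz)[, band, drop = FALSE]
  pm <- rbind(sx, sy, -dz)[, band, drop = FALSE]
  f_plus <- trilinear_gather(phantom_ft$values, to_idx(rotation %*% pp))
  f_minus <- trilinear_gather(phantom_ft$values, to_idx(rotation %*% pm))

  az <- atan2(sy, sx)[band]
  chiv <- chi(smag[band], model, az)
  jv <- complex(length.out = n * n)
  jv[band] <- ctf_p(chiv, model) * f_minus + ctf_q(chiv, model) * f_plus
  jmat <- matrix(jv, n, n)
  # J's phases are referred to the particle centre; add the ramp that puts
  # the particle at pixel (n/2+1, n/2+1) of the stored image
  jmat <- phase_center2(jmat, c(1 - n / 2, 1 - n / 2))
  img <- take_real(ifft2(jmat), tol = 1e-6, what = "forward image")
  structure(img, pixel_size = apix, center = c(n / 2 + 1, n / 2 + 1))
}

#' Additive white Gaussian noise
#'
#' @param image real matrix.
#' @param noise_sd standard deviation in image units (>= 0).
#' @param seed integer seed; the same seed gives identical output.
#' @return the noisy image (attributes preserved).
#' @export
add_noise <- function(image, noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(image)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- image + stats::rnorm(length(image), 0, noise_sd)
  attributes(out) <- attributes(image)
  out
}

#' ZYZ Euler angles to rotation matrix
#'
#' \eqn{R = R_z(\phi)\,R_y(\theta)\,R_z(\psi)}; the matrix is applied to
#' sampling-plane coordinates in the forward model and the reconstruction.
#'
#' @param phi,theta,psi angles in radians.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' Rotation matrix to ZYZ Euler angles
#'
#' Inverse of [euler_to_matrix()] (principal branch, theta in `[0, pi]`).
#'
#' @param r 3x3 rotation matrix.
#' @return numeric vector `c(phi, theta, psi)` in radians.
#' @export
matrix_to_euler <- function(r) {
  theta <- acos(max(-1, min(1, r[3, 3])))
  if (sin(theta) > 1e-9) {
    phi <- atan2(r[2, 3], r[1, 3])
    psi <- atan2(r[3, 2], -r[3, 1])
  } else {
    phi <- atan2(r[2, 1], r[1, 1])
    psi <- 0
  }
  c(phi = phi, theta = theta, psi = psi)
}

#' Uniform random rotations
#'
#' Rotation matrices drawn uniformly from SO(3) via normalised Gaussian
#' quaternions.
#'
#' @param n number of rotations.
#' @param seed integer seed.
#' @return list of 3x3 rotation matrices.
#' @export
random_rotations <- function(n, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  })
}

#' Simulate a particle dataset from a chiral phantom
#'
#' Generates a phantom (unless one is supplied), draws uniform random
#' orientations and per-particle defocus values, and renders every particle
#' with the curved-Ewald forward model. The defaults define a grid-scaled
#' imaging condition in which Ewald-sphere curvature is strongly
#' significant: on a 64-voxel, 1 A/px grid a 24 A particle imaged with
#' wavelength 0.25 A at 120-160 A defocus has the same dimensionless
#' curvature ratio \eqn{D\lambda/d^2} (1.5 at Nyquist) as a 450-550 A
#' particle at 3 A and 300 keV, while the defocus range exceeds the
#' full-separation threshold (96 A at Nyquist) and the delocalised
#' sidebands still fit in the box.
#'
#' @param n_particles number of particle images.
#' @param seed integer seed controlling phantom, orientations and defocus.
#' @param phantom optional 3D phantom array; default
#'   `make_chiral_phantom(size, pixel_size, diameter, seed)`.
#' @param size grid side in voxels/pixels.
#' @param pixel_size pixel/voxel size in Angstrom.
#' @param diameter particle diameter in Angstrom.
#' @param wavelength electron wavelength in Angstrom.
#' @param defocus_range two-element range (A) from which per-particle
#'   defocus values are drawn uniformly.
#' @param cs spherical aberration in Angstrom.
#' @param amp_contrast amplitude-contrast fraction (0 for the pure
#'   weak-phase model).
#' @param curvature `"on"`, `"off"` or `"inverted"`.
#' @param noise_sd white-noise standard deviation added to each image.
#' @param oversample padding factor for the phantom transform.
#' @return list with `images` (N x N x P array), `particles` (a particle
#'   table data.frame, angles in radians), `rotations`, `phantom`,
#'   `phantom_ft`, and the generating parameters.
#' @export
simulate_dataset <- function(n_particles = 48, seed = 1, phantom = NULL,
                             size = 64, pixel_size = 1, diameter = 24,
                             wavelength = 0.25,
                             defocus_range = c(120, 160), cs = 0,
                             amp_contrast = 0, curvature = "on",
                             noise_sd = 0, oversample = 2) {
  if (is.null(phantom))
    phantom <- make_chiral_phantom(size, pixel_size, diameter, seed)
  pft <- prepare_volume_ft(phantom, pixel_size, oversample)
  rots <- random_rotations(n_particles, seed + 1000L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed + 2000L)
  dfs <- stats::runif(n_particles, defocus_range[1], defocus_range[2])
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  images <- array(0, c(size, size, n_particles))
  for (i in seq_len(n_particles)) {
    mod_i <- optical_model(wavelength = wavelength, defocus = dfs[i],
                           cs = cs, amp_contrast = amp_contrast)
    img <- forward_image(pft, rots[[i]], mod_i, curvature = curvature)
    if (noise_sd > 0) img <- add_noise(img, noise_sd, seed + 3000L + i)
    images[, , i] <- img
  }
  eul <- t(vapply(rots, matrix_to_euler, numeric(3)))
  particles <- data.frame(
    stack_index = seq_len(n_particles), defocus_A = dfs,
    diameter_A = diameter, pixel_size_A = pixel_size,
    voltage_kev = NA_real_, cs_A = cs, amp_contrast = amp_contrast,
    wavelength_A = wavelength,
    euler_phi_rad = eul[, 1], euler_theta_rad = eul[, 2],
    euler_psi_rad = eul[, 3])
  list(images = images, particles = particles, rotations = rots,
       phantom = phantom, phantom_ft = pft, wavelength = wavelength,
       pixel_size = pixel_size, diameter = diameter, curvature = curvature,
       seed = seed)
}
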