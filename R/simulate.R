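# Synthetic multi-coil Cartesian acquisitions with known ground truth.
#
# Two coil models are provided. "smooth-gaussian" coils emulate a head
# array: broad Gaussian magnitude lobes arranged on a ring with smooth
# linear phase, so the sum of squares stays bounded away from zero over
# the phantom. "harmonic" coils carry unit-modulus pure spatial
# harmonics exp(2i*pi*m_l*y/ny), m_l = 0..L-1; by the Fourier shift
# theorem each coil's spectrum is the image spectrum circularly shifted
# by m_l phase-encode lines, so every missing line is an exact linear
# combination of acquired lines whenever the number of coils is at least
# the reduction factor. That makes the harmonic fixture an analytic
# correctness oracle for GRAPPA-type reconstruction.

# Ellipse table: modified Shepp-Logan geometry with graded inserts so the
# phantom exposes at least five distinct intensity levels.
shepp_logan_ellipses <- function() {
  # A, a, b, x0, y0, phi (degrees)
  rbind(
    c(1.00, 0.6900, 0.9200,  0.00,  0.0000,   0),
    c(-0.80, 0.6624, 0.8740, 0.00, -0.0184,   0),
    c(-0.20, 0.1100, 0.3100, 0.22,  0.0000, -18),
    c(-0.20, 0.1600, 0.4100, -0.22, 0.0000,  18),
    c(0.10, 0.2100, 0.2500,  0.00,  0.3500,   0),
    c(0.10, 0.0460, 0.0460,  0.00,  0.1000,   0),
    c(0.10, 0.0460, 0.0460,  0.00, -0.1000,   0),
    c(0.15, 0.0460, 0.0230, -0.08, -0.6050,   0),
    c(0.15, 0.0230, 0.0230,  0.00, -0.6060,   0),
    c(0.15, 0.0230, 0.0460,  0.06, -0.6050,   0)
  )
}

pixel_grid <- function(ny, nx) {
  y <- ((seq_len(ny) - 1) - floor(ny / 2)) / (ny / 2)
  x <- ((seq_len(nx) - 1) - floor(nx / 2)) / (nx / 2)
  list(y = matrix(y, ny, nx), x = matrix(x, ny, nx, byrow = TRUE))
}

#' Analytic test phantoms
#'
#' `"shepp-logan"` evaluates a modified Shepp-Logan ellipse table (with
#' graded small inserts) analytically at each pixel centre; values are
#' nonnegative with maximum 1 and at least five distinct tissue levels.
#' `"blobs"` is a seeded mixture of broad Gaussians normalised to max 1;
#' its spectrum decays essentially to zero at the k-space edge, which is
#' the property the harmonic exactness fixture relies on.
#'
#' @param ny,nx matrix size, both `>= 16`.
#' @param kind `"shepp-logan"` or `"blobs"`.
#' @param n_blobs number of Gaussian components (blobs only).
#' @param seed RNG seed (blobs only); the result is a deterministic
#'   function of the arguments.
#' @return real `ny x nx` matrix in `[0, 1]`.
#' @export
make_phantom <- function(ny, nx, kind = c("shepp-logan", "blobs"),
                         n_blobs = 6, seed = 1) {
  kind <- match.arg(kind)
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 16L || nx < 16L) stop("phantom size must be at least 16 x 16")
  g <- pixel_grid(ny, nx)
  img <- matrix(0, ny, nx)
  if (kind == "shepp-logan") {
    for (i in seq_len(nrow(shepp_logan_ellipses()))) {
      e <- shepp_logan_ellipses()[i, ]
      phi <- e[6] * pi / 180
      xr <- cos(phi) * (g$x - e[4]) + sin(phi) * (g$y - e[5])
      yr <- -sin(phi) * (g$x - e[4]) + cos(phi) * (g$y - e[5])
      inside <- (xr / e[2])^2 + (yr / e[3])^2 <= 1
      img <- img + e[1] * inside
    }
    img <- pmax(img, 0)
  } else {
    params <- with_seed(seed, list(
      cx = stats::runif(n_blobs, -0.5, 0.5),
      cy = stats::runif(n_blobs, -0.5, 0.5),
      w = stats::runif(n_blobs, 0.12, 0.25),
      a = stats::runif(n_blobs, 0.4, 1)
    ))
    for (i in seq_len(n_blobs)) {
      d2 <- (g$x - params$cx[i])^2 + (g$y - params$cy[i])^2
      img <- img + params$a[i] * exp(-d2 / (2 * params$w[i]^2))
    }
    img <- img / max(img)
  }
  img
}

#' Simulated coil sensitivity maps
#'
#' `"smooth-gaussian"` places `n_coils` broad complex Gaussian lobes on a
#' ring outside the field of view with smooth linear phase (seeded
#' jitter on centres, widths and phase slopes). `"harmonic"` gives coil
#' `l` (1-based) the unit-modulus map `exp(2i*pi*(l-1)*y/ny)` where `y`
#' is the 0-based row index: pure spatial harmonics along phase encode.
#'
#' @param n_coils number of coils, `>= 1`.
#' @param ny,nx matrix size.
#' @param kind `"smooth-gaussian"` or `"harmonic"`.
#' @param seed RNG seed for the smooth-gaussian jitter.
#' @return object of class `coil_sensitivities`: list with complex
#'   `maps` of dim `c(n_coils, ny, nx)`, `kind` and `seed`.
#' @export
make_sensitivities <- function(n_coils, ny, nx,
                               kind = c("smooth-gaussian", "harmonic"),
                               seed = 1) {
  kind <- match.arg(kind)
  n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stop("n_coils must be >= 1")
  maps <- array(complex(real = 0), dim = c(n_coils, ny, nx))
  if (kind == "harmonic") {
    yrow <- (seq_len(ny) - 1)
    for (l in seq_len(n_coils)) {
      m <- l - 1L
      phase <- exp(2i * pi * m * yrow / ny)
      maps[l, , ] <- matrix(phase, ny, nx)
    }
  } else {
    g <- pixel_grid(ny, nx)
    par <- with_seed(seed, list(
      jit = stats::runif(n_coils, -0.2, 0.2),
      w = stats::runif(n_coils, 0.9, 1.2),
      px = stats::runif(n_coils, -0.6, 0.6),
      py = stats::runif(n_coils, -0.6, 0.6),
      p0 = stats::runif(n_coils, 0, 2 * pi)
    ))
    for (l in seq_len(n_coils)) {
      th <- 2 * pi * (l - 1) / n_coils + par$jit[l]
      cx <- 1.3 * cos(th); cy <- 1.3 * sin(th)
      d2 <- (g$x - cx)^2 + (g$y - cy)^2
      mag <- exp(-d2 / (2 * par$w[l]^2))
      ph <- par$px[l] * g$x + par$py[l] * g$y + par$p0[l]
      maps[l, , ] <- mag * exp(1i * ph)
    }
  }
  structure(list(maps = maps, kind = kind, seed = seed,
                 n_coils = n_coils, ny = ny, nx = nx),
            class = "coil_sensitivities")
}

#' Exact spatial-harmonic fixture k-space
#'
#' A fully sampled multi-coil acquisition built for correctness proofs
#' of GRAPPA-type reconstruction. A reference spectrum of i.i.d.
#' complex Gaussian samples is restricted to a centred guard band
#' (exactly zero within `margin_ky` lines of the ky edges and
#' `margin_kx` columns of the kx edges); coil `l` then receives that
#' spectrum circularly shifted by `m_l = l - 1` phase-encode lines
#' (times the fixed `(-1)^m` phase that the centred-spectrum convention
#' assigns to odd harmonics). This is exactly the k-space of
#' [simulate_kspace()] with `"harmonic"` sensitivities applied to the
#' band-limited reference image.
#'
#' With at least as many coils as the reduction factor, every missing
#' line is an exact linear combination of acquired coil lines, and the
#' guard band makes zero-filling outside the matrix exact too, so
#' GRAPPA must reconstruct to machine precision.
#'
#' @param ny,nx matrix size.
#' @param n_coils number of harmonic coils (use `>=` the largest band
#'   ORF to be reconstructed).
#' @param seed RNG seed for the reference spectrum.
#' @param margin_ky,margin_kx guard-band widths; `margin_ky` must
#'   exceed the largest harmonic shift plus the kernel's ky reach, and
#'   `margin_kx` the kernel's kx reach.
#' @return a fully sampled `kspace`.
#' @export
make_harmonic_fixture <- function(ny, nx, n_coils, seed = 1,
                                  margin_ky = 16, margin_kx = 12) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (2 * margin_ky >= ny || 2 * margin_kx >= nx) {
    stop("guard margins leave no k-space support")
  }
  s0 <- matrix(0+0i, ny, nx)
  rows <- (margin_ky + 1L):(ny - margin_ky)
  cols <- (margin_kx + 1L):(nx - margin_kx)
  vals <- with_seed(seed, complex(real = stats::rnorm(length(rows) * length(cols)),
                                  imaginary = stats::rnorm(length(rows) * length(cols))))
  s0[rows, cols] <- vals
  data <- array(complex(real = 0), dim = c(n_coils, ny, nx))
  for (l in seq_len(n_coils)) {
    m <- l - 1L
    data[l, , ] <- (-1)^m * s0[((seq_len(ny) - 1L - m) %% ny) + 1L, ]
  }
  new_kspace(data, rep(TRUE, ny),
             meta = list(fixture = "harmonic", seed = seed,
                         margin_ky = margin_ky, margin_kx = margin_kx))
}

new_kspace <- function(data, sampled, meta = list()) {
  structure(list(data = data, sampled = sampled, meta = meta),
            class = "kspace")
}

#' Simulate multi-coil k-space
#'
#' Each coil's k-space is the centered unitary Fourier transform of the
#' sensitivity-weighted image, plus i.i.d. circular complex Gaussian
#' noise with standard deviation `noise_sigma` per real/imaginary
#' component. All lines are flagged as sampled; apply a mask with
#' [apply_mask()].
#'
#' @param image real `ny x nx` image.
#' @param sens a `coil_sensitivities` object of matching size.
#' @param noise_sigma per-component noise standard deviation, `>= 0`.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return a `kspace` object: complex `data` of dim `c(n_coils, ny, nx)`,
#'   logical per-line `sampled`, and provenance `meta`.
#' @export
simulate_kspace <- function(image, sens, noise_sigma = 0, seed = 1) {
  stopifnot(inherits(sens, "coil_sensitivities"))
  image <- as.matrix(image)
  ny <- nrow(image); nx <- ncol(image)
  if (sens$ny != ny || sens$nx != nx) {
    stop("image and sensitivity dimensions disagree")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  L <- sens$n_coils
  data <- array(complex(real = 0), dim = c(L, ny, nx))
  for (l in seq_len(L)) {
    data[l, , ] <- image_to_kspace(sens$maps[l, , ] * image)
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed, complex(
      real = stats::rnorm(L * ny * nx, sd = noise_sigma),
      imaginary = stats::rnorm(L * ny * nx, sd = noise_sigma)
    ))
    data <- data + array(noise, dim = c(L, ny, nx))
  }
  new_kspace(data, rep(TRUE, ny),
             meta = list(sens_kind = sens$kind, noise_sigma = noise_sigma,
                         seed = seed))
}

#' Apply an undersampling mask to k-space
#'
#' Zeroes every unsampled phase-encode line across all coils and copies
#' the mask's sampled flags; acquired lines are bit-identical to the
#' input.
#'
#' @param kspace a `kspace` object.
#' @param mask a `sampling_mask` with matching `n_ky`.
#' @return a `kspace` with unsampled lines exactly zero-filled.
#' @export
apply_mask <- function(kspace, mask) {
  stopifnot(inherits(kspace, "kspace"), inherits(mask, "sampling_mask"))
  ny <- dim(kspace$data)[2]
  if (ny != mask$n_ky) stop("kspace and mask n_ky disagree")
  data <- kspace$data
  data[, !mask$sampled, ] <- 0+0i
  new_kspace(data, mask$sampled, meta = kspace$meta)
}

#' Per-coil images and sum-of-squares image from k-space
#'
#' `coil_images()` inverse-transforms each coil; `kspace_sos()` combines
#' them with [sos_combine()].
#'
#' @param kspace a `kspace` object.
#' @return `coil_images()`: complex array `c(n_coils, ny, nx)`;
#'   `kspace_sos()`: real `ny x nx` matrix.
#' @export
coil_images <- function(kspace) {
  stopifnot(inherits(kspace, "kspace"))
  d <- kspace$data
  out <- array(complex(real = 0), dim = dim(d))
  for (l in seq_len(dim(d)[1])) {
    out[l, , ] <- kspace_to_image(d[l, , ])
  }
  out
}

#' @rdname coil_images
#' @export
kspace_sos <- function(kspace) {
  sos_combine(coil_images(kspace))
}

#' @export
print.kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace> %d coils, %d x %d, %d/%d ky lines sampled\n",
              d[1], d[2], d[3], sum(x$sampled), d[2]))
  invisible(x)
}
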