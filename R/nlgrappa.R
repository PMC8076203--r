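# NL-GRAPPA: the polynomial-kernel (gamma = r = 1, degree = 2) variant
# of GRAPPA realised as an explicit second-order feature map over the
# GRAPPA neighbourhood. Each calibration row / synthesis neighbourhood
# is expanded into the fixed block order
#   [1 | S_l(b,h) | S_l(b,h)^2 | S_l(b,h) S_l(b,h+1) | S_l(b,h) S_l(b,h+2)]
# with h varying fastest, then b, then coil l inside each block. The
# h+1 and h+2 partners beyond the last kernel column are read from the
# same acquired line along the fully sampled kx axis (zero outside the
# matrix), so all four second-order blocks keep the same size and the
# feature length is exactly 1 + 4 * L * n_blocks * n_cols. The
# first-order block is the conventional GRAPPA model, so the GRAPPA
# solution is nested inside the NL-GRAPPA feature space.

#' NL-GRAPPA configuration
#'
#' Parameters of the polynomial kernel whose explicit truncated feature
#' space the second-order model spans. Only `degree = 2` (with
#' `gamma = 1`, `r_offset = 1`) is implemented: the expansion above is
#' the degree-2 truncation actually used for reconstruction.
#'
#' @param gamma,r_offset polynomial-kernel parameters (informational;
#'   the expansion is the fixed degree-2 truncation).
#' @param degree polynomial degree; values other than 2 are rejected.
#' @param ridge default relative Tikhonov regularisation used by
#'   [nlgrappa_reconstruct()]; underdetermined second-order fits are
#'   routine at small ACS, and a small ridge keeps them stable.
#' @return object of class `nl_config`.
#' @export
nl_config <- function(gamma = 1, r_offset = 1, degree = 2, ridge = 1e-6) {
  if (degree != 2) {
    stop("only degree = 2 is implemented: the explicit second-order ",
         "feature expansion")
  }
  structure(list(gamma = gamma, r_offset = r_offset, degree = 2L,
                 ridge = ridge), class = "nl_config")
}

#' Second-order feature length
#'
#' `1 + 4 * n_coils * n_blocks * n_cols`: one constant, one first-order
#' block and three second-order blocks of equal size.
#'
#' @param n_coils,n_blocks,n_cols neighbourhood dimensions.
#' @export
nl_feature_length <- function(n_coils, n_blocks, n_cols) {
  1L + 4L * as.integer(n_coils) * as.integer(n_blocks) * as.integer(n_cols)
}

#' Explicit second-order feature map of one neighbourhood
#'
#' Expands the complex source values of a single target position into
#' the NL-GRAPPA feature vector. The input carries the kernel window
#' plus the two kx-extension columns used by the h+1 / h+2 product
#' terms (already zero-filled where they fall outside the matrix).
#'
#' @param neighborhood complex array of dim
#'   `c(n_coils, n_blocks, n_cols + 2)`: source values
#'   `S_l(ky + b*R*dky, kx + h*dkx)` for `h` covering the kernel window
#'   and two extra trailing columns.
#' @param config an `nl_config`.
#' @return complex vector of length
#'   `nl_feature_length(n_coils, n_blocks, n_cols)` in the documented
#'   block order.
#' @examples
#' nb <- array(c(2 + 0i, 3i, 0i, 0i), dim = c(1, 1, 4))
#' feature_map(nb, nl_config()) # 1, 2, 3i, 4, -9, 6i, 0, 0, 0
#' @export
feature_map <- function(neighborhood, config = nl_config()) {
  stopifnot(inherits(config, "nl_config"))
  d <- dim(neighborhood)
  if (length(d) != 3L || d[3] < 3L) {
    stop("neighborhood must be c(n_coils, n_blocks, n_cols + 2)")
  }
  L <- d[1]; nb <- d[2]; nh <- d[3] - 2L
  s <- s1 <- s2 <- complex(length.out = 0)
  for (l in seq_len(L)) {
    for (b in seq_len(nb)) {
      v <- neighborhood[l, b, ]
      s <- c(s, v[seq_len(nh)])
      s1 <- c(s1, v[seq_len(nh) + 1L])
      s2 <- c(s2, v[seq_len(nh) + 2L])
    }
  }
  c(1+0i, s, s * s, s * s1, s * s2)
}

#' NL-GRAPPA reconstruction
#'
#' Identical per-band driver to [grappa_reconstruct()], but every
#' calibration row and synthesis neighbourhood is expanded through the
#' explicit second-order feature map, and the weight vector per (band
#' ORF, offset, target coil) has the full feature length. k-space is
#' normalised by its maximum modulus before feature construction and
#' rescaled afterwards: the raw second-order map is not homogeneous in
#' the data scale, and the pre-scaling restores effective
#' scale-equivariance and keeps first- and second-order columns
#' comparably conditioned.
#'
#' @inheritParams grappa_reconstruct
#' @param config an [nl_config()].
#' @param ridge relative Tikhonov regularisation; defaults to the
#'   config's value (`1e-6`). Use 0 for pure minimum-norm least squares.
#' @return a `kspace` with missing lines synthesised; per-band fit
#'   diagnostics in `attr(, "fits")`.
#' @export
nlgrappa_reconstruct <- function(kspace, mask, geom = kernel_geometry(),
                                 config = nl_config(), ridge = NULL) {
  stopifnot(inherits(config, "nl_config"))
  if (is.null(ridge)) ridge <- config$ridge
  scale <- max(Mod(kspace$data))
  if (scale == 0) return(recon_driver(kspace, mask, geom, 2L, ridge))
  ks <- new_kspace(kspace$data / scale, kspace$sampled, kspace$meta)
  out <- recon_driver(ks, mask, geom, order = 2L, ridge = ridge)
  fits <- attr(out, "fits")
  out <- new_kspace(out$data * scale, out$sampled, out$meta)
  attr(out, "fits") <- fits
  out
}
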