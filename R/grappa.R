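# GRAPPA: fill missing phase-encode lines as coil-wise linear
# combinations of acquired neighbours, with weights fitted on the ACS
# block (b = A x). One weight set is fitted per (band ORF, line offset
# r, target coil); MVDS masks simply repeat the procedure per band with
# the band's own ORF, innermost band first, all calibrated from the same
# central ACS block.

#' GRAPPA kernel geometry
#'
#' The fitting neighbourhood: `n_cols` k-space columns along the fully
#' sampled frequency-encode axis (offsets `h`, centred on the target
#' column) by `n_blocks` acquired-line blocks along phase encode
#' (offsets `b`, in units of `ORF` lines; `n_blocks = 2` uses the
#' acquired line at/below the target and the next acquired line above).
#' The conventional "15 x 2" kernel is `kernel_geometry(15, 2)`.
#'
#' @param n_cols number of kx columns (odd values centre the window).
#' @param n_blocks number of ky blocks.
#' @return object of class `kernel_geometry` with integer `col_offsets`
#'   and `block_offsets`.
#' @export
kernel_geometry <- function(n_cols = 15, n_blocks = 2) {
  n_cols <- as.integer(n_cols); n_blocks <- as.integer(n_blocks)
  if (n_cols < 1L || n_blocks < 1L) stop("kernel sizes must be positive")
  h1 <- -floor((n_cols - 1) / 2)
  b1 <- -as.integer(ceiling((n_blocks - 2) / 2))
  structure(list(
    col_offsets = seq.int(h1, h1 + n_cols - 1L),
    block_offsets = seq.int(b1, b1 + n_blocks - 1L),
    n_cols = n_cols, n_blocks = n_blocks
  ), class = "kernel_geometry")
}

# First-order source matrix: rows are kx positions, columns the features
# (l, b, h) with h varying fastest, then b, then l. `lines` are 1-based
# ky indices per block; out-of-matrix lines/columns contribute zeros.
source_matrix <- function(data, lines, kx_idx, col_offsets) {
  L <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  nb <- length(lines); nh <- length(col_offsets)
  out <- matrix(0+0i, nrow = length(kx_idx), ncol = L * nb * nh)
  zero_line <- rep(0+0i, nx)
  col <- 0L
  for (l in seq_len(L)) {
    for (bi in seq_len(nb)) {
      ky <- lines[bi]
      line <- if (ky >= 1L && ky <= ny) data[l, ky, ] else zero_line
      for (h in col_offsets) {
        col <- col + 1L
        idx <- kx_idx + h
        ok <- idx >= 1L & idx <= nx
        v <- rep(0+0i, length(kx_idx))
        v[ok] <- line[idx[ok]]
        out[, col] <- v
      }
    }
  }
  out
}

# Model matrix for one reference line: first-order for `order = 1`, the
# explicit second-order polynomial expansion for `order = 2`.
model_matrix <- function(data, lines, kx_idx, geom, order) {
  if (order == 1L) {
    return(source_matrix(data, lines, kx_idx, geom$col_offsets))
  }
  ext_offsets <- seq.int(min(geom$col_offsets), max(geom$col_offsets) + 2L)
  S_ext <- source_matrix(data, lines, kx_idx, ext_offsets)
  nh <- geom$n_cols
  nhe <- length(ext_offsets)
  nlb <- ncol(S_ext) / nhe
  base <- rep((seq_len(nlb) - 1L) * nhe, each = nh)
  i0 <- base + seq_len(nh)      # h
  i1 <- base + seq_len(nh) + 1L # h + 1
  i2 <- base + seq_len(nh) + 2L # h + 2
  S <- S_ext[, i0, drop = FALSE]
  cbind(rep(1+0i, nrow(S)), S, S * S,
        S * S_ext[, i1, drop = FALSE],
        S * S_ext[, i2, drop = FALSE])
}

# Stride-ORF calibration positions: 1-based reference-line indices ky0
# such that every source line ky0 + b*orf and every target ky0 + r
# (r = 1..orf-1) lies inside the ACS block.
calibration_positions <- function(mask, geom, orf) {
  alo <- mask$acs_range[1]; ahi <- mask$acs_range[2]
  b1 <- min(geom$block_offsets); b2 <- max(geom$block_offsets)
  first <- alo - b1 * orf
  last <- ahi - max(b2 * orf, orf - 1L)
  if (last < first) return(integer(0))
  seq.int(first, last, by = orf)
}

#' Build the GRAPPA calibration system for one band offset
#'
#' Slides the kernel through the ACS block at stride `orf` and collects
#' one fitting equation per (reference line, kx column) pair; rows only
#' use source and target positions fully inside the ACS block and the kx
#' range, so no zero-padded calibration rows occur. With too few ACS
#' lines to host a single kernel instance the build fails with an
#' "ACS block too small" error -- the few-ACS failure mode in which VDS
#' schemes degrade.
#'
#' @param kspace a `kspace` (ACS lines must contain data).
#' @param mask a `sampling_mask`.
#' @param geom a `kernel_geometry`.
#' @param orf the band's outer reduction factor.
#' @param offset target line offset `r` in `1..orf-1`.
#' @param order `1` (GRAPPA) or `2` (NL-GRAPPA feature expansion).
#' @return object of class `calibration_system`: model matrix `A`
#'   (`M x N`), target matrix `b` (`M x n_coils`, one column per target
#'   coil), and bookkeeping (`positions`, `kx_idx`, `orf`, `offset`,
#'   `order`, `geom`).
#' @export
build_calibration_system <- function(kspace, mask, geom, orf, offset,
                                     order = 1) {
  stopifnot(inherits(kspace, "kspace"), inherits(mask, "sampling_mask"),
            inherits(geom, "kernel_geometry"))
  orf <- as.integer(orf); offset <- as.integer(offset)
  order <- as.integer(order)
  if (offset < 1L || offset >= orf) stop("offset must be in 1..orf-1")
  nx <- dim(kspace$data)[3]
  pos <- calibration_positions(mask, geom, orf)
  if (length(pos) == 0L) {
    stop("ACS block too small for the kernel at ORF ", orf, call. = FALSE)
  }
  h1 <- min(geom$col_offsets); h2 <- max(geom$col_offsets)
  kx_idx <- seq.int(1L - h1, nx - h2)
  if (length(kx_idx) == 0L) stop("kx range too small for the kernel")
  A <- do.call(rbind, lapply(pos, function(ky0) {
    model_matrix(kspace$data, ky0 + geom$block_offsets * orf, kx_idx,
                 geom, order)
  }))
  L <- dim(kspace$data)[1]
  b <- do.call(rbind, lapply(pos, function(ky0) {
    t(matrix(kspace$data[, ky0 + offset, kx_idx], nrow = L))
  }))
  structure(list(A = A, b = b, positions = pos, kx_idx = kx_idx,
                 orf = orf, offset = offset, order = order, geom = geom,
                 n_coils = L),
            class = "calibration_system")
}

# SVD least-squares / Tikhonov solver shared by both models. `ridge` is
# relative to the largest singular value; with ridge = 0 the minimum-norm
# solution with relative cutoff `svd_cutoff` is returned.
solve_weights <- function(A, B, ridge = 0, svd_cutoff = 1e-10) {
  sv <- La.svd(A)
  d <- sv$d
  uhB <- Conj(t(sv$u)) %*% B
  if (ridge > 0) {
    lam <- ridge * d[1]
    f <- d / (d^2 + lam^2)
    rank <- sum(d > svd_cutoff * d[1])
  } else {
    keep <- d > svd_cutoff * max(d, 0)
    f <- ifelse(keep, 1 / d, 0)
    rank <- sum(keep)
  }
  X <- Conj(t(sv$vt)) %*% (uhB * f)
  list(weights = X, rank = rank)
}

#' Fit GRAPPA weights from a calibration system
#'
#' Minimum-norm least squares via the SVD pseudo-inverse (relative
#' singular-value cutoff `1e-10`) when `ridge = 0`, otherwise the
#' Tikhonov solution with regularisation `ridge` relative to the largest
#' singular value. Rank deficiency is reported through the effective
#' rank, never as a failure; underdetermined systems (common for the
#' second-order model at small ACS) yield the minimum-norm solution.
#'
#' @param system a `calibration_system`.
#' @param ridge relative Tikhonov parameter, `>= 0`.
#' @return object of class `weight_fit`: `weights` (`N x n_coils`
#'   complex), per-coil `residual` norms, `relative_residual`
#'   (`||Ax-b|| / ||b||` over all targets), `rank`, plus the system
#'   bookkeeping.
#' @export
fit_weights <- function(system, ridge = 0) {
  stopifnot(inherits(system, "calibration_system"))
  sol <- solve_weights(system$A, system$b, ridge = ridge)
  R <- system$A %*% sol$weights - system$b
  resid <- sqrt(colSums(Mod(R)^2))
  bnorm <- sqrt(sum(Mod(system$b)^2))
  structure(list(weights = sol$weights, residual = resid,
                 relative_residual = if (bnorm > 0) sqrt(sum(resid^2)) / bnorm else 0,
                 rank = sol$rank, orf = system$orf, offset = system$offset,
                 order = system$order, geom = system$geom),
            class = "weight_fit")
}

# Fit weights for all offsets 1..orf-1 of one band in a single SVD.
fit_band_weights <- function(kspace, mask, geom, orf, order, ridge,
                             svd_cutoff = 1e-10) {
  sys1 <- build_calibration_system(kspace, mask, geom, orf, 1L, order)
  offsets <- seq_len(orf - 1L)
  B <- do.call(cbind, c(list(sys1$b), lapply(offsets[-1], function(r) {
    build_calibration_system(kspace, mask, geom, orf, r, order)$b
  })))
  sol <- solve_weights(sys1$A, B, ridge = ridge, svd_cutoff = svd_cutoff)
  L <- sys1$n_coils
  res <- sqrt(sum(Mod(sys1$A %*% sol$weights - B)^2))
  bn <- sqrt(sum(Mod(B)^2))
  list(
    weights = lapply(offsets, function(r) {
      sol$weights[, (r - 1L) * L + seq_len(L), drop = FALSE]
    }),
    rank = sol$rank,
    n_equations = nrow(sys1$A),
    n_features = ncol(sys1$A),
    relative_residual = if (bn > 0) res / bn else 0
  )
}

# Fill the missing lines of one band (both sides) in place.
fill_band <- function(data, band, weights, geom, order, sampled) {
  orf <- band$orf
  for (side in c("low", "high")) {
    lines <- band[[paste0("lines_", side)]]
    region <- band[[paste0("region_", side)]]
    if (is.null(region) || length(lines) == 0L) next
    phase <- lines[1] %% orf  # lines and regions are stored 0-based
    for (ky in region[1]:region[2]) {
      ky1 <- ky + 1L
      if (sampled[ky1]) next
      r <- (ky - phase) %% orf
      # r == 0 is an unacquired comb position beyond the outermost
      # sampled line; no offset weights apply, the line stays zero
      if (r == 0L) next
      ky0 <- ky1 - r  # 1-based reference (may be virtual at the edge)
      F <- model_matrix(data, ky0 + geom$block_offsets * orf,
                        seq_len(dim(data)[3]), geom, order)
      W <- weights[[r]]
      data[, ky1, ] <- t(F %*% W)
    }
  }
  data
}

# Shared per-band reconstruction driver (Fig.-14 procedure): for each
# band, calibrate weights for the band's ORF from the central ACS block,
# then synthesise that band's missing lines, innermost band first.
recon_driver <- function(kspace, mask, geom, order, ridge,
                         svd_cutoff = 1e-10) {
  stopifnot(inherits(kspace, "kspace"), inherits(mask, "sampling_mask"),
            inherits(geom, "kernel_geometry"))
  ny <- dim(kspace$data)[2]
  if (ny != mask$n_ky) stop("kspace and mask n_ky disagree")
  data <- kspace$data
  data[, !mask$sampled, ] <- 0+0i  # contract: unsampled lines are zero
  fits <- list()
  for (band in mask$bands) {
    if (band$orf == 1L || band$n_lines == 0L) next
    fit <- fit_band_weights(kspace, mask, geom, band$orf, order, ridge,
                            svd_cutoff)
    fits[[band_label(band$orf)]] <- fit
    data <- fill_band(data, band, fit$weights, geom, order, mask$sampled)
  }
  out <- new_kspace(data, kspace$sampled, meta = kspace$meta)
  attr(out, "fits") <- fits
  out
}

#' Synthesize the missing lines of one band
#'
#' Uses fitted weights to fill every missing line in the band's region
#' from acquired (or previously filled) neighbouring lines; acquired
#' samples are left untouched (data consistency). Out-of-matrix source
#' lines contribute zeros, so lines beyond the outermost sampled line
#' are synthesised from the available sources only.
#'
#' @param kspace a `kspace` whose unsampled lines are zero-filled.
#' @param mask the `sampling_mask` that produced it.
#' @param weights list indexed by offset `r` of `N x n_coils` weight
#'   matrices (as returned in `fit_band_weights()$weights`, or built
#'   from [fit_weights()] results).
#' @param geom the `kernel_geometry` the weights were fitted with.
#' @param orf the band's ORF.
#' @param band_index which band of `mask$bands` to synthesise.
#' @param order model order, `1` or `2`.
#' @return a `kspace` with the band's missing lines filled.
#' @export
synthesize_region <- function(kspace, mask, weights, geom, orf,
                              band_index, order = 1) {
  stopifnot(inherits(kspace, "kspace"), inherits(mask, "sampling_mask"))
  band <- mask$bands[[band_index]]
  if (band$orf != orf) stop("band_index does not match the given orf")
  if (length(weights) < orf - 1L) {
    stop("missing weights: need one matrix per offset 1..orf-1")
  }
  data <- fill_band(kspace$data, band, weights, geom, order, mask$sampled)
  new_kspace(data, kspace$sampled, meta = kspace$meta)
}

#' GRAPPA reconstruction
#'
#' For each band of the mask (innermost first), fits linear GRAPPA
#' weights for the band's ORF from the shared central ACS block and
#' fills the band's missing lines. Acquired lines pass through
#' unchanged. Lines outside every band region (possible for an MVDS
#' scheme that does not reach the k-space edge) remain zero.
#'
#' @param kspace a `kspace` with unsampled lines zero-filled (see
#'   [apply_mask()]).
#' @param mask the `sampling_mask`.
#' @param geom a `kernel_geometry` (default 15 x 2).
#' @param ridge relative Tikhonov regularisation (default 0: minimum
#'   norm least squares).
#' @return a `kspace` with missing lines synthesised; per-band fit
#'   diagnostics are attached as `attr(, "fits")`.
#' @export
grappa_reconstruct <- function(kspace, mask, geom = kernel_geometry(),
                               ridge = 0) {
  recon_driver(kspace, mask, geom, order = 1L, ridge = ridge)
}
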