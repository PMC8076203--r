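# Coil combination and image-quality metrics. Artifact power (AP) is
# the squared magnitude error normalised by the reference energy over a
# region of interest; SNR is the dB ratio of reconstruction energy to
# error energy. Both are scale-sensitive by design, which is why the
# reconstruction pipeline keeps a fixed unitary transform scale rather
# than normalising images.

roi_index <- function(dim_img, roi) {
  if (is.null(roi)) {
    return(list(y = seq_len(dim_img[1]), x = seq_len(dim_img[2])))
  }
  stopifnot(length(roi) == 4)
  if (roi[1] < 1 || roi[2] > dim_img[1] || roi[3] < 1 ||
      roi[4] > dim_img[2] || roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("roi must be c(y0, y1, x0, x1) within the image, 1-based inclusive")
  }
  list(y = roi[1]:roi[2], x = roi[3]:roi[4])
}

#' Sum-of-squares coil combination
#'
#' Pixelwise root of the sum over coils of squared magnitudes,
#' `sqrt(sum_l |I_l|^2)`: the standard reference image for multi-coil
#' data.
#'
#' @param coil_imgs complex (or real) array of dim `c(n_coils, ny, nx)`.
#' @return real nonnegative `ny x nx` matrix.
#' @export
sos_combine <- function(coil_imgs) {
  d <- dim(coil_imgs)
  if (is.null(d) || length(d) != 3L || d[1] < 1L) {
    stop("coil_imgs must be a non-empty c(n_coils, ny, nx) array")
  }
  out <- matrix(0, d[2], d[3])
  for (l in seq_len(d[1])) {
    out <- out + Mod(coil_imgs[l, , ])^2
  }
  sqrt(out)
}

#' Artifact power
#'
#' `sum_ROI (|ref| - |recon|)^2 / sum_ROI |ref|^2`. Magnitudes enter the
#' numerator; 0 means magnitudes agree exactly on the ROI, 1 is the
#' value for an identically zero reconstruction. Reported in tables as
#' a percentage.
#'
#' @param recon,reference images of identical dimension (real or
#'   complex; magnitudes are taken).
#' @param roi `NULL` for the whole matrix or `c(y0, y1, x0, x1)`
#'   (1-based, inclusive).
#' @return nonnegative scalar fraction.
#' @export
artifact_power <- function(recon, reference, roi = NULL) {
  recon <- as.matrix(recon); reference <- as.matrix(reference)
  if (!all(dim(recon) == dim(reference))) stop("images differ in shape")
  ix <- roi_index(dim(reference), roi)
  refm <- Mod(reference[ix$y, ix$x])
  recm <- Mod(recon[ix$y, ix$x])
  den <- sum(refm^2)
  if (den == 0) stop("reference has zero energy on the ROI")
  sum((refm - recm)^2) / den
}

#' Signal-to-noise ratio of a reconstruction (dB)
#'
#' `10 log10( sum_ROI |recon|^2 / sum_ROI |recon - ref|^2 )`, with the
#' complex (or signed) difference in the denominator. Returns `Inf`
#' when the reconstruction equals the reference on the ROI -- a defined
#' result, serialised as the string `"inf"` in JSON reports.
#'
#' @inheritParams artifact_power
#' @return scalar dB value, possibly `Inf`.
#' @export
snr_db <- function(recon, reference, roi = NULL) {
  recon <- as.matrix(recon); reference <- as.matrix(reference)
  if (!all(dim(recon) == dim(reference))) stop("images differ in shape")
  ix <- roi_index(dim(recon), roi)
  num <- sum(Mod(recon[ix$y, ix$x])^2)
  den <- sum(Mod(recon[ix$y, ix$x] - reference[ix$y, ix$x])^2)
  if (den == 0) return(Inf)
  10 * log10(num / den)
}

#' Signed and absolute difference maps
#'
#' Pixelwise `|recon| - |reference|` (signed) and its absolute value,
#' for display of artifact location and severity.
#'
#' @inheritParams artifact_power
#' @return list with `signed` and `absolute` real matrices.
#' @export
difference_map <- function(recon, reference) {
  recon <- as.matrix(recon); reference <- as.matrix(reference)
  if (!all(dim(recon) == dim(reference))) stop("images differ in shape")
  s <- Mod(recon) - Mod(reference)
  list(signed = s, absolute = abs(s))
}

#' Full metrics report for a reconstruction
#'
#' Bundles AP (as a fraction and percentage), SNR, the ROI and the
#' mask's line accounting into one JSON-serialisable list.
#'
#' @inheritParams artifact_power
#' @param mask optional `sampling_mask` supplying line counts and R_net.
#' @return list with `ap`, `ap_percent`, `snr_db`, `roi`, and (when a
#'   mask is given) `r_net` and `lines`.
#' @export
metrics_report <- function(recon, reference, roi = NULL, mask = NULL) {
  ap <- artifact_power(recon, reference, roi)
  snr <- snr_db(recon, reference, roi)
  out <- list(
    ap = ap,
    ap_percent = round_half_up(100 * ap, 2),
    snr_db = if (is.finite(snr)) round_half_up(snr, 2) else "inf",
    roi = if (is.null(roi)) "full" else roi
  )
  if (!is.null(mask)) {
    rep_ <- scheme_report(mask)
    out$r_net <- rep_$r_net
    out$lines <- as.list(rep_$counts)
    out$total_lines <- rep_$total
  }
  out
}
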