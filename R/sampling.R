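# Line-based Cartesian undersampling along the phase-encode (ky) axis.
#
# All masks share one geometry: a fully sampled, contiguous ACS block
# centred on the DC line (0-based index floor(n_ky/2)), flanked by
# "bands" of uniformly strided lines. Each band with outer reduction
# factor (ORF) R keeps one line in every R; bands are ordered innermost
# (lowest ORF) to outermost (highest ORF). Per side, a band samples the
# innermost index of each consecutive R-block, so consecutive sampled
# lines within a band sit exactly R indices apart and the first line of
# the next band continues the comb.
#
# Odd per-band line counts put the extra line on the high-index side.
# For uniform and VDS masks the outermost band is derived, not user-set:
# its total count is ceil(remaining_span / R) computed over both sides
# jointly (this is what reproduces printed line budgets such as
# 20 ACS + 59 outer lines for a 256-line acquisition at R = 4), then
# split floor/ceil between the low/high sides.

band_label <- function(orf) paste0("R", orf)

# Place `count` lines of stride `orf` on one side of the ACS block.
# `p` is the 0-based index immediately outside the previously placed
# region (below it for side = "low", above for side = "high").
place_side <- function(p, count, orf, side, n_ky) {
  if (count == 0L) {
    return(list(lines = integer(0), region = NULL, p = p))
  }
  if (side == "high") {
    lines <- p + orf * (seq_len(count) - 1L)
    if (max(lines) > n_ky - 1L) {
      stop("band with ORF ", orf, " cannot place ", count,
           " lines on the high side of the ACS block", call. = FALSE)
    }
    region <- c(p, min(n_ky - 1L, p + orf * count - 1L))
    p_new <- p + orf * count
  } else {
    lines <- p - orf * (seq_len(count) - 1L)
    if (min(lines) < 0L) {
      stop("band with ORF ", orf, " cannot place ", count,
           " lines on the low side of the ACS block", call. = FALSE)
    }
    region <- c(max(0L, p - orf * count + 1L), p)
    p_new <- p - orf * count
  }
  list(lines = sort(lines), region = region, p = p_new)
}

# Core mask builder. `fixed_bands` is a list of c(orf, n_lines) placed
# inner to outer with exact counts; `outer_orf`, if given, adds a derived
# band that fills the rest of k-space.
build_mask <- function(n_ky, acs_count, fixed_bands = list(),
                       outer_orf = NULL, type = "mvds", r_nom = NULL) {
  n_ky <- as.integer(n_ky)
  acs_count <- as.integer(acs_count)
  if (is.na(n_ky) || n_ky < 1L) stop("n_ky must be a positive integer")
  if (is.na(acs_count) || acs_count < 1L || acs_count > n_ky) {
    stop("acs_count must satisfy 0 < acs_count <= n_ky")
  }
  orfs <- vapply(fixed_bands, function(b) as.integer(b[[1]]), integer(1))
  nls <- vapply(fixed_bands, function(b) as.integer(b[[2]]), integer(1))
  if (any(orfs < 2L)) stop("band ORFs must be >= 2")
  if (any(nls < 0L)) stop("band line counts must be >= 0")
  all_orfs <- c(orfs, if (!is.null(outer_orf)) as.integer(outer_orf))
  if (length(all_orfs) > 1L && any(diff(all_orfs) <= 0L)) {
    stop("band ORFs must be strictly increasing from innermost to outermost")
  }
  if (acs_count + sum(nls) > n_ky) {
    stop("requested lines exceed n_ky")
  }

  center <- n_ky %/% 2L                   # 0-based DC line
  acs_lo <- center - acs_count %/% 2L     # 0-based inclusive
  acs_hi <- acs_lo + acs_count - 1L
  if (acs_lo < 0L || acs_hi > n_ky - 1L) {
    stop("ACS block does not fit in n_ky lines")
  }

  p_low <- acs_lo - 1L
  p_high <- acs_hi + 1L
  bands <- list()

  side_fits <- function(p, count, orf, side) {
    count == 0L ||
      (if (side == "high") p + orf * (count - 1L) <= n_ky - 1L
       else p - orf * (count - 1L) >= 0L)
  }

  add_band <- function(orf, c_low, c_high) {
    # odd remainders go to the high-index side, unless that side cannot
    # host the extra line while the low side can (swap keeps the total)
    if (c_high > c_low && !side_fits(p_high, c_high, orf, "high") &&
        side_fits(p_low, c_high, orf, "low")) {
      tmp <- c_low; c_low <- c_high; c_high <- tmp
    }
    lo <- place_side(p_low, c_low, orf, "low", n_ky)
    hi <- place_side(p_high, c_high, orf, "high", n_ky)
    p_low <<- lo$p
    p_high <<- hi$p
    bands[[length(bands) + 1L]] <<- list(
      orf = as.integer(orf),
      n_lines = c_low + c_high,
      lines_low = lo$lines, lines_high = hi$lines,
      region_low = lo$region, region_high = hi$region
    )
  }

  for (i in seq_along(orfs)) {
    n <- nls[i]
    add_band(orfs[i], floor(n / 2), as.integer(ceiling(n / 2)))
  }

  if (!is.null(outer_orf)) {
    outer_orf <- as.integer(outer_orf)
    span_low <- p_low + 1L
    span_high <- n_ky - p_high
    span <- span_low + span_high
    if (span > 0L) {
      total <- as.integer(ceiling(span / outer_orf))
      c_low <- total %/% 2L
      c_high <- total - c_low
      add_band(outer_orf, c_low, c_high)
      k <- length(bands)
      # the derived band owns everything out to the k-space edges
      if (!is.null(bands[[k]]$region_low)) bands[[k]]$region_low[1] <- 0L
      if (!is.null(bands[[k]]$region_high)) bands[[k]]$region_high[2] <- n_ky - 1L
    }
  }

  sampled <- rep(FALSE, n_ky)
  region <- rep("unsampled", n_ky)
  acs_idx <- (acs_lo:acs_hi) + 1L
  sampled[acs_idx] <- TRUE
  region[acs_idx] <- "ACS"
  for (b in bands) {
    lab <- band_label(b$orf)
    for (rg in list(b$region_low, b$region_high)) {
      if (!is.null(rg)) {
        idx <- (rg[1]:rg[2]) + 1L
        region[idx][region[idx] == "unsampled"] <- lab
      }
    }
    sampled[c(b$lines_low, b$lines_high) + 1L] <- TRUE
  }

  structure(list(
    n_ky = n_ky,
    sampled = sampled,
    region = region,
    acs_range = c(acs_lo, acs_hi) + 1L,
    bands = bands,
    scheme = list(type = type, acs_count = acs_count, r_nom = r_nom,
                  bands = Map(function(o, n) c(orf = o, n_lines = n),
                              as.list(orfs), as.list(nls)))
  ), class = "sampling_mask")
}

#' Traditional uniform undersampling mask
#'
#' Fully samples `acs_count` central auto-calibration (ACS) lines and keeps
#' one line in every `r_nom` outside the ACS block. The outer line count is
#' `ceiling((n_ky - acs_count)/r_nom)`, split evenly between the two sides
#' with any odd remainder on the high-index side.
#'
#' @param n_ky number of phase-encode lines in the fully sampled grid.
#' @param acs_count number of central fully sampled ACS lines.
#' @param r_nom nominal (outer) reduction factor, `>= 1`.
#' @return A `sampling_mask`: a list with per-line logical `sampled`,
#'   per-line `region` labels (`"ACS"`, `"R<orf>"`, `"unsampled"`), the
#'   1-based inclusive `acs_range`, and per-band line bookkeeping.
#' @examples
#' m <- make_uniform_mask(256, 16, 4)
#' sum(m$sampled) # 76
#' @export
make_uniform_mask <- function(n_ky, acs_count, r_nom) {
  r_nom <- as.integer(r_nom)
  if (is.na(r_nom) || r_nom < 1L) stop("r_nom must be a positive integer")
  build_mask(n_ky, acs_count, list(), outer_orf = r_nom,
             type = "uniform", r_nom = r_nom)
}

#' Multiple variable density (MVDS) undersampling mask
#'
#' Keeps the full ACS block unchanged and surrounds it with bands of
#' strictly increasing ORF: a low ORF immediately flanking the ACS lines
#' (where k-space carries most image energy) and higher ORFs further out.
#' Band line counts are honoured exactly; each band's lines are split
#' half per side (odd remainder to the high-index side).
#'
#' @inheritParams make_uniform_mask
#' @param bands list of `c(orf, n_lines)` pairs, innermost first, ORFs
#'   strictly increasing, each ORF `>= 2`.
#' @examples
#' m <- make_mvds_mask(256, 16, list(c(2, 20), c(4, 20), c(6, 20)))
#' scheme_report(m)$counts
#' @export
make_mvds_mask <- function(n_ky, acs_count, bands) {
  build_mask(n_ky, acs_count, bands, outer_orf = NULL, type = "mvds")
}

#' Variable density (VDS) undersampling mask
#'
#' The scheme of Park et al.: the caller trades ACS lines for a band of
#' `low_orf_lines` lines at `low_orf` flanking the (reduced) ACS block;
#' the rest of k-space is filled at the nominal factor `r_nom` out to the
#' edges, with the same global-ceiling line count as the uniform mask.
#'
#' @inheritParams make_uniform_mask
#' @param low_orf_lines number of lines in the low-ORF band (0 gives the
#'   plain uniform mask).
#' @param low_orf stride of the inner band; must be `< r_nom`.
#' @examples
#' m <- make_vds_mask(256, 12, 6, 2, 4)
#' sum(m$sampled) # 76
#' @export
make_vds_mask <- function(n_ky, acs_count, low_orf_lines, low_orf, r_nom) {
  low_orf <- as.integer(low_orf)
  r_nom <- as.integer(r_nom)
  if (low_orf >= r_nom) stop("low_orf must be smaller than r_nom")
  fixed <- if (low_orf_lines > 0) list(c(low_orf, low_orf_lines)) else list()
  build_mask(n_ky, acs_count, fixed, outer_orf = r_nom,
             type = "vds", r_nom = r_nom)
}

#' Net reduction factor
#'
#' The realised acceleration `n_full / sampled_total`: the nominal factor
#' corrected for the extra ACS lines actually acquired.
#'
#' @param n_full total number of phase-encode lines at full sampling.
#' @param sampled_total number of lines actually acquired.
#' @return The unrounded ratio; reports round it half-up to 2 decimals.
#' @examples
#' net_reduction_factor(256, 76) # 3.368...
#' @export
net_reduction_factor <- function(n_full, sampled_total) {
  if (sampled_total <= 0) stop("sampled_total must be positive")
  if (sampled_total > n_full) stop("sampled_total cannot exceed n_full")
  n_full / sampled_total
}

#' Line-budget summary of a sampling mask
#'
#' Per-region acquired-line counts, the total, and the net reduction
#' factor (rounded half-up to 2 decimals, as printed in comparison
#' tables). The result is a plain list, directly serialisable to JSON.
#'
#' @param mask a `sampling_mask`.
#' @return list with `counts` (named integer vector: ACS then each band),
#'   `total`, `n_ky`, `r_net`.
#' @export
scheme_report <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  counts <- c(ACS = length(mask$acs_range[1]:mask$acs_range[2]))
  for (b in mask$bands) {
    counts[band_label(b$orf)] <- b$n_lines
  }
  total <- sum(mask$sampled)
  stopifnot(sum(counts) == total)
  list(counts = counts, total = as.integer(total), n_ky = mask$n_ky,
       r_net = round_half_up(net_reduction_factor(mask$n_ky, total), 2))
}

#' @export
print.sampling_mask <- function(x, ...) {
  rep_ <- scheme_report(x)
  cat(sprintf("<sampling_mask> %s scheme, %d of %d ky lines acquired (R_net %.2f)\n",
              x$scheme$type, rep_$total, x$n_ky, rep_$r_net))
  cat("  ", paste(sprintf("%s:%d", names(rep_$counts), rep_$counts),
                  collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Write / read a sampling mask as JSON
#'
#' The JSON schema uses 0-based line indices:
#' `{"n_ky", "acs": {"start", "count"}, "bands": [{"orf", "line_indices"}],
#'   "sampled_lines", "r_net"}`.
#'
#' @param mask a `sampling_mask`.
#' @param path file path.
#' @return `read_mask_json()` returns the reconstructed `sampling_mask`.
#' @export
write_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  obj <- list(
    n_ky = mask$n_ky,
    acs = list(start = mask$acs_range[1] - 1L,
               count = mask$acs_range[2] - mask$acs_range[1] + 1L),
    scheme = mask$scheme[c("type", "acs_count", "r_nom")],
    bands = lapply(mask$bands, function(b) list(
      orf = b$orf,
      n_lines = b$n_lines,
      line_indices = sort(c(b$lines_low, b$lines_high))
    )),
    sampled_lines = which(mask$sampled) - 1L,
    r_net = net_reduction_factor(mask$n_ky, sum(mask$sampled))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_ky", "acs", "sampled_lines")) {
    if (is.null(obj[[f]])) stop("mask JSON is missing field '", f, "'")
  }
  sc <- obj$scheme
  bands <- obj$bands
  type <- if (is.null(sc$type)) "mvds" else sc$type
  if (type == "uniform") {
    make_uniform_mask(obj$n_ky, obj$acs$count, sc$r_nom)
  } else if (type == "vds") {
    nb <- if (is.null(dim(bands))) length(bands$orf) else nrow(bands)
    if (nb > 1L) {
      make_vds_mask(obj$n_ky, obj$acs$count, bands$n_lines[1],
                    bands$orf[1], sc$r_nom)
    } else {
      make_vds_mask(obj$n_ky, obj$acs$count, 0L, sc$r_nom - 1L, sc$r_nom)
    }
  } else {
    spec <- Map(function(o, n) c(o, n), bands$orf, bands$n_lines)
    make_mvds_mask(obj$n_ky, obj$acs$count, spec)
  }
}
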