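# Shared fixtures and small independent oracles.

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# Random small complex k-space (not band-limited; generic data).
random_kspace <- function(n_coils, ny, nx, seed = 1) {
  vals <- mvdsgrappa:::with_seed(seed, complex(
    real = stats::rnorm(n_coils * ny * nx),
    imaginary = stats::rnorm(n_coils * ny * nx)
  ))
  mvdsgrappa:::new_kspace(array(vals, dim = c(n_coils, ny, nx)),
                          rep(TRUE, ny))
}

# Random valid sampling scheme for property tests: parameters drawn so
# every band is guaranteed to fit on both sides of the ACS block.
random_scheme <- function(seed) {
  mvdsgrappa:::with_seed(seed, {
    n_ky <- sample(seq(96, 256, by = 2), 1)
    acs <- 2 * sample(3:8, 1)
    n_bands <- sample(1:3, 1)
    orfs <- sort(sample(2:8, n_bands))
    side_budget <- (n_ky - acs) %/% 2
    bands <- list()
    used <- 0
    for (orf in orfs) {
      cap <- (side_budget - used) %/% orf
      c_side <- if (cap > 0) sample(0:min(cap, 4), 1) else 0
      n_lines <- 2 * c_side + sample(0:1, 1) * (c_side > 0)
      bands[[length(bands) + 1]] <- c(orf, n_lines)
      used <- used + orf * c_side + orf * (n_lines %% 2)
    }
    list(n_ky = n_ky, acs = acs, bands = bands)
  })
}

# Brute-force per-label tally, independent of scheme_report's counters.
tally_regions <- function(mask) {
  labs <- unique(mask$region[mask$sampled])
  out <- vapply(labs, function(l) {
    sum(mask$sampled & mask$region == l)
  }, integer(1))
  names(out) <- labs
  out
}
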