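---
title: "Variable-density sampling and GRAPPA-family reconstruction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-density sampling and GRAPPA-family reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdsgrappa)
```

## The reconstruction model

Cartesian parallel MRI undersamples whole phase-encode (ky) lines;
each of `L` coils sees the object through a smooth complex sensitivity
map, so coil k-spaces are correlated and a missing sample can be
interpolated from acquired neighbours across coils. GRAPPA expresses
the missing sample at offset `r` above an acquired line as

`S_j(ky + r) = sum_{l, b, h} w_{j,r}(l, b, h) * S_l(ky + b*R, kx + h)`

where `b` ranges over acquired-line blocks (spaced `R` lines apart, the
band's outer reduction factor) and `h` over columns of the fully
sampled frequency-encode axis. The weights are fitted by least squares
on the central auto-calibration (ACS) block, where both sources and
targets were actually acquired.

NL-GRAPPA replaces the source vector by an explicit second-order
polynomial feature map: the constant 1, the first-order sources, their
squares, and products of each source with its `h+1` and `h+2` column
neighbours, giving `1 + 4*L*n_blocks*n_cols` features. This is the
degree-2 truncation associated with a polynomial kernel
(`gamma = r = 1, d = 2`). Because the first-order block *is* the
GRAPPA model, the linear solution lives inside the nonlinear feature
space, and the nonlinear training residual can never exceed the linear
one — an invariant the test suite asserts on every calibration system
it builds.

Two points in the product terms deserve emphasis. First, the `h+1` and
`h+2` partners for the last kernel columns fall outside the kernel
window; they are read from the same acquired line's full kx axis (zero
beyond the matrix edge), so all four second-order blocks keep the same
size. Second, the raw second-order map is not homogeneous in the data
scale, so `nlgrappa_reconstruct()` normalises k-space by its maximum
modulus before building features and rescales the output afterwards;
this restores effective scale-equivariance (asserted to 1e-8 in the
tests) and keeps first- and second-order columns comparably
conditioned.

## Sampling schemes

All masks share one geometry: a contiguous ACS block centred on the DC
line (0-based index `floor(n_ky/2)`), flanked by bands of uniformly
strided lines, innermost ORF lowest. Per side, a band samples the
innermost index of each consecutive `R`-block, so consecutive sampled
lines sit exactly `R` apart and the first line of the next band
continues the comb — which also guarantees that the `b = 1` source of
a missing line at a region boundary is an acquired line of the next
band.

* `make_uniform_mask(n_ky, acs, R)`: the outer line count is
  `ceiling((n_ky - acs)/R)` computed over both sides jointly and split
  floor/ceiling between the low/high sides. The joint ceiling (rather
  than per-side ceilings) is what reproduces the printed budgets of
  the published scheme comparisons, e.g. 20 ACS + 59 outer lines for a
  256-line grid at R = 4.
* `make_vds_mask()`: a fixed-count low-ORF band around a reduced ACS
  block, then the same derived outer band.
* `make_mvds_mask()`: all band counts are user-specified and honoured
  exactly; lines outside the outermost band remain unsampled (and are
  not reconstructed).

Tie-breaks and degenerate cases are fixed so masks are pure functions
of their arguments: odd band counts put the extra line on the
high-index side, unless that side cannot host it at the band's stride
while the low side can (one published 13/13/13 scheme at R4/R6/R8 on a
256-line grid needs this swap); an ACS block covering the whole grid
yields full sampling; a zero-count band is skipped. `R_net =
n_full/n_sampled` is computed from the realised mask count and
reported rounded half-up to two decimals, matching table conventions.

## Calibration and synthesis details

Calibration slides the kernel through the ACS block at stride `R`
(mirroring the undersampled geometry the weights will be applied to),
keeping only instances whose sources *and* targets lie wholly inside
the ACS block and the kx range — no zero-padded calibration rows. One
system per band is solved for all offsets and target coils at once.
If no instance fits, reconstruction fails with an "ACS block too
small" error; this is the regime in which ACS-trading schemes degrade.

The solver is an SVD pseudo-inverse: with `ridge = 0`, minimum-norm
least squares with relative singular-value cutoff `1e-10` (reproducible
behaviour on rank-deficient systems; rank is reported, never an
error); with `ridge > 0`, Tikhonov regularisation with the parameter
expressed relative to the largest singular value. GRAPPA defaults to
`ridge = 0`; NL-GRAPPA to `1e-6`, because second-order systems are
routinely underdetermined at small ACS and an interpolating min-norm
fit benefits from mild damping.

Synthesis fills bands innermost first, so an outer band's
centre-facing sources are already-reconstructed (inner) lines rather
than zeros. Out-of-matrix sources contribute zeros; missing lines
beyond the outermost sampled line reuse the outer band's weights with
whatever sources exist. Acquired samples are never touched
(data-consistency is asserted bit-for-bit in the tests).

## What the simulator emulates — and what it does not

`simulate_kspace()` models: an analytic object (modified Shepp-Logan
with graded inserts, or a seeded Gaussian-blob mixture), smooth
complex coil sensitivities on a ring (magnitude lobes plus linear
phase; SoS bounded away from zero over the object), centred unitary
Fourier transforms (so Parseval holds exactly and metric scales are
fixed), and i.i.d. circular complex Gaussian noise per k-space sample,
seeded explicitly — no global RNG state. It does not model pulse
sequence contrast, relaxation, off-resonance, gradient nonlinearity,
coil noise correlation, or 3-D volumes. Passing tests therefore
demonstrate correctness of the sampling/reconstruction machinery and
qualitative scheme behaviour, not quantitative in-vivo artifact
levels, which depend on the specific anatomy and coil array.

The harmonic fixture (`make_harmonic_fixture()`) is the correctness
oracle: coil `l` carries the unit-modulus harmonic
`exp(2i*pi*(l-1)*y/ny)`, so by the shift theorem its spectrum is the
reference spectrum circularly shifted by `l-1` lines, and with at
least `R` coils every missing line is an *exact* linear combination of
acquired lines. Two conditions make the end-to-end check achieve
machine precision rather than merely "small" error: the fixture
spectrum is white noise restricted to a guard band (exactly zero near
the k-space edges, so zero-filled out-of-matrix sources are exact and
circular shifts cannot wrap energy), and the ACS is sized so each
band's calibration is overdetermined (`M >= N`); an underdetermined
minimum-norm fit matches the calibration data perfectly but is not
forced to the structural weights, and need not generalise. The
acceptance checks use ACS 32 on a 128-line grid for this reason.

## Study conditions for the scheme comparison

The matched-budget comparison runs at a 128-line grid with 8
smooth-gaussian coils, ACS 8, kernel 15 x 2, noise sigma 0.01 (giving
per-pixel image SNR of a few tens, a realistic regime), ten noise
seeds, and a 38-line budget (`R_net` 3.37): uniform = ACS 8 + 30 lines
at R4; VDS = ACS 6 + 2 lines at R2 + 30 at R4; the MVDS series splits
(R2, R4, R6) counts as (0,30,0), (2,26,2), ..., (12,6,12), each
tiling the grid exactly. These are half-scale versions of the
published 256-line comparisons. The comparison uses linear GRAPPA: at
ACS 8 the second-order feature space (961 features) is underdetermined
by an order of magnitude for every band, so nonlinear reconstructions
are dominated by min-norm generalisation error rather than by the
sampling pattern, whereas the linear model (240 features) is
(near-)determined and isolates the pattern effect under study. The
expected behaviour — MVDS below uniform, reduced-ACS VDS above it, and
a non-increasing AP trend as the low-ORF band grows — is asserted as
rank statements over seed means, never as absolute AP values.

## Known limitations

* 1-D Cartesian line sampling only: no 2-D (ky-kz), non-Cartesian,
  Poisson-disc or partial-Fourier patterns.
* GRAPPA-family reconstruction only; no SENSE-type unfolding,
  iterative self-consistency, calibrationless completion, or learned
  methods.
* The second-order expansion implements exactly the published
  truncation (within-coil, within-block products at column gaps 1 and
  2); no cross-coil or cross-block second-order terms, and no other
  kernels.
* The k-space container is a versioned RDS file — convenient and
  lossless for R workflows, but not a cross-language archival format.
* Computation is dense linear algebra in R; matrices beyond ~512 lines
  with large coil counts will want a compiled or GPU implementation.
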