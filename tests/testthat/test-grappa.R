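# Calibration, weight fitting and per-band synthesis.

test_that("calibration system has the combinatorial row count", {
  # 1 coil, blocks {0,1}, 1 column, ORF 2, ACS of 8 lines x 16 columns:
  # reference positions slide at stride 2 -> 3 positions, all 16 columns
  # valid -> M = 48 rows, 2 features
  ks <- random_kspace(1, 32, 16, seed = 2)
  mask <- make_uniform_mask(32, 8, 2)
  geom <- kernel_geometry(1, 2)
  sys <- build_calibration_system(ks, mask, geom, orf = 2, offset = 1)
  expect_equal(nrow(sys$A), 48)
  expect_equal(ncol(sys$A), 2)
  expect_equal(length(sys$positions), 3)
  # row content: sources at ky0 and ky0 + 2, target at ky0 + 1
  ky0 <- sys$positions[1]
  expect_identical(sys$A[1:16, 1], ks$data[1, ky0, 1:16])
  expect_identical(sys$A[1:16, 2], ks$data[1, ky0 + 2, 1:16])
  expect_identical(sys$b[1:16, 1], ks$data[1, ky0 + 1, 1:16])
})

test_that("kernel geometry and kx windowing follow the 15 x 2 convention", {
  g <- kernel_geometry(15, 2)
  expect_identical(g$col_offsets, -7:7)
  expect_identical(g$block_offsets, 0:1)
  ks <- random_kspace(2, 64, 64, seed = 3)
  mask <- make_uniform_mask(64, 16, 2)
  sys <- build_calibration_system(ks, mask, g, 2, 1)
  # calibration rows avoid zero padding: kx restricted to 8..57
  expect_equal(nrow(sys$A) %% 50, 0)
  expect_identical(sys$kx_idx, 8:57)
})

test_that("too small an ACS block fails with a clear error", {
  ks <- random_kspace(2, 64, 64, seed = 4)
  mask <- make_uniform_mask(64, 4, 6)  # needs 7 ACS lines for blocks {0,1}
  expect_error(build_calibration_system(ks, mask, kernel_geometry(5, 2), 6, 1),
               "ACS block too small")
  expect_error(grappa_reconstruct(apply_mask(ks, mask), mask,
                                  kernel_geometry(5, 2)),
               "ACS block too small")
})

test_that("fit_weights solves trivial and structured systems", {
  sys <- structure(list(A = diag(2) + 0i, b = matrix(c(3, 4) + 0i, 2, 1),
                        orf = 2L, offset = 1L, order = 1L,
                        geom = kernel_geometry(1, 2), n_coils = 1L),
                   class = "calibration_system")
  fit <- fit_weights(sys)
  expect_equal(as.vector(fit$weights), c(3 + 0i, 4 + 0i))
  expect_equal(fit$rank, 2)

  # all-zero ACS: A = 0, b = 0, weights 0, no failure
  ks0 <- mvdsgrappa:::new_kspace(array(0+0i, c(1, 32, 16)), rep(TRUE, 32))
  mask <- make_uniform_mask(32, 8, 2)
  sys0 <- build_calibration_system(ks0, mask, kernel_geometry(1, 2), 2, 1)
  expect_true(all(sys0$A == 0) && all(sys0$b == 0))
  fit0 <- fit_weights(sys0)
  expect_true(all(fit0$weights == 0))
  expect_equal(fit0$rank, 0)
})

test_that("lines that average their neighbours give weights (0.5, 0.5)", {
  # single coil, every line an arithmetic progression along ky:
  # S(ky) = f(kx) + ky * g(kx), so the missing line is the mean of the
  # two acquired neighbours and the closed-form weights are (1/2, 1/2)
  ny <- 32; nx <- 16
  fg <- mvdsgrappa:::with_seed(6, list(
    f = complex(real = rnorm(nx), imaginary = rnorm(nx)),
    g = complex(real = rnorm(nx), imaginary = rnorm(nx))
  ))
  data <- array(0+0i, c(1, ny, nx))
  for (ky in 1:ny) data[1, ky, ] <- fg$f + ky * fg$g
  ks <- mvdsgrappa:::new_kspace(data, rep(TRUE, ny))
  mask <- make_uniform_mask(ny, 8, 2)
  sys <- build_calibration_system(ks, mask, kernel_geometry(1, 2), 2, 1)
  fit <- fit_weights(sys)
  expect_equal(as.vector(fit$weights), c(0.5 + 0i, 0.5 + 0i),
               tolerance = 1e-10)
})

test_that("weights match a brute-force normal-equations oracle", {
  ks <- random_kspace(2, 32, 16, seed = 7)
  mask <- make_uniform_mask(32, 12, 2)
  geom <- kernel_geometry(3, 2)
  sys <- build_calibration_system(ks, mask, geom, 2, 1)
  expect_gte(nrow(sys$A), ncol(sys$A))
  fit <- fit_weights(sys)
  oracle <- solve(Conj(t(sys$A)) %*% sys$A, Conj(t(sys$A)) %*% sys$b)
  expect_lt(max(Mod(fit$weights - oracle)), 1e-8)
})

test_that("harmonic fixture calibration is exactly consistent", {
  ks <- make_harmonic_fixture(64, 64, 4, seed = 11)
  mask <- make_uniform_mask(64, 16, 2)
  sys <- build_calibration_system(ks, mask, kernel_geometry(15, 2), 2, 1)
  fit <- fit_weights(sys)
  expect_lt(sqrt(sum(fit$residual^2)), 1e-10 * sqrt(sum(Mod(sys$b)^2)))
})

test_that("GRAPPA is exact on the harmonic fixture for all mask families", {
  geom <- kernel_geometry(15, 2)
  ks <- make_harmonic_fixture(64, 64, 4, seed = 11)
  mask <- make_uniform_mask(64, 16, 2)
  rec <- grappa_reconstruct(apply_mask(ks, mask), mask, geom)
  expect_lt(rel_err(rec$data, ks$data), 1e-8)

  ks8 <- make_harmonic_fixture(128, 128, 8, seed = 12)
  mvds <- make_mvds_mask(128, 32, list(c(2, 10), c(4, 10), c(6, 6)))
  rec8 <- grappa_reconstruct(apply_mask(ks8, mvds), mvds, geom)
  expect_lt(rel_err(rec8$data, ks8$data), 1e-6)

  vds <- make_vds_mask(128, 24, 6, 2, 4)
  recv <- grappa_reconstruct(apply_mask(ks8, vds), vds, geom)
  expect_lt(rel_err(recv$data, ks8$data), 1e-6)
})

test_that("acquired samples pass through reconstruction bit-identically", {
  img <- make_phantom(64, 64, "shepp-logan")
  sens <- make_sensitivities(4, 64, 64, "smooth-gaussian", seed = 5)
  full <- simulate_kspace(img, sens, 0.02, seed = 9)
  mask <- make_mvds_mask(64, 16, list(c(2, 8), c(4, 4)))
  under <- apply_mask(full, mask)
  rec <- grappa_reconstruct(under, mask, kernel_geometry(7, 2))
  expect_identical(rec$data[, mask$sampled, ], under$data[, mask$sampled, ])
  # every line inside band regions got filled
  filled <- apply(Mod(rec$data[1, , , drop = FALSE]), 2, sum) > 0
  expect_true(all(filled[mask$region != "unsampled"]))
})

test_that("synthesize_region respects its contracts", {
  ks <- make_harmonic_fixture(64, 64, 4, seed = 13)
  mask <- make_uniform_mask(64, 16, 2)
  geom <- kernel_geometry(15, 2)
  under <- apply_mask(ks, mask)
  fitb <- mvdsgrappa:::fit_band_weights(under, mask, geom, 2L, 1L, 0)
  out <- synthesize_region(under, mask, fitb$weights, geom, 2, 1)
  expect_lt(rel_err(out$data, ks$data), 1e-8)
  # zero weights leave missing lines zero
  zw <- list(matrix(0+0i, nrow(fitb$weights[[1]]), ncol(fitb$weights[[1]])))
  z <- synthesize_region(under, mask, zw, geom, 2, 1)
  expect_identical(z$data, under$data)
  # full mask: nothing to synthesize anywhere
  full <- make_uniform_mask(64, 64, 1)
  reca <- grappa_reconstruct(apply_mask(ks, full), full, geom)
  expect_identical(reca$data, ks$data)
  # missing weights for a needed offset
  expect_error(synthesize_region(under, mask, list(), geom, 2, 1),
               "missing weights")
})

test_that("ACS-only masks leave outer k-space zero", {
  ks <- make_harmonic_fixture(64, 64, 4, seed = 14)
  mask <- make_mvds_mask(64, 16, list())
  rec <- grappa_reconstruct(apply_mask(ks, mask), mask, kernel_geometry(15, 2))
  expect_identical(rec$data[, mask$sampled, ], ks$data[, mask$sampled, ])
  expect_true(all(rec$data[, !mask$sampled, ] == 0))
})

test_that("mean AP grows with the reduction factor (noise monotonicity)", {
  n <- 64
  img <- make_phantom(n, n, "shepp-logan")
  sens <- make_sensitivities(8, n, n, "smooth-gaussian", seed = 1)
  geom <- kernel_geometry(15, 2)
  masks <- lapply(c(2, 4, 6), function(r) make_uniform_mask(n, 16, r))
  aps <- sapply(1:10, function(s) {
    full <- simulate_kspace(img, sens, 0.01, seed = 300 + s)
    ref <- kspace_sos(full)
    sapply(masks, function(m) {
      rec <- grappa_reconstruct(apply_mask(full, m), m, geom)
      artifact_power(kspace_sos(rec), ref)
    })
  })
  m <- rowMeans(aps)
  expect_true(m[1] <= m[2] && m[2] <= m[3])
})
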