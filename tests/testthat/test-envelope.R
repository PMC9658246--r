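test_that("flat and degenerate profiles are their own envelope", {
  expect_equal(envelope_1d(rep(7, 50), 10), rep(7, 50))
  # a single deep spike (valley) is bridged, not followed
  prof <- rep(50, 100); prof[50] <- 70
  expect_equal(envelope_1d(prof, 20), rep(50, 100))
  expect_error(envelope_1d(rep(1, 10), 20), "visibility window")
  expect_error(envelope_1d(c(1, NA, 3), 2), "hole-free")
})

test_that("the envelope touches every ridge top of a periodic profile", {
  x <- 1:240
  prof <- 50 + 4 * (1 - cos(2 * pi * x / 24))   # tops at multiples of 24
  env <- envelope_1d(prof, 48)
  tops <- seq(24, 216, by = 24)
  expect_equal(env[tops], prof[tops], tolerance = 1e-12)
  expect_true(all(env <= prof + 1e-12))
  # between tops the envelope stays near the top plane, far from valleys
  expect_lt(max(env[24:216] - 50), 0.5)
})

test_that("the envelope never undercuts the profile and is stable under
           re-application on equal-height ridges", {
  x <- 1:256
  for (prof in list(
    50 + 4 * (1 - cos(2 * pi * x / 24)),
    40 + 0.009 * (x - 128)^2 / 2 + 4 * (1 - cos(2 * pi * x / 24)),
    40 + 0.3 * x + 4 * (1 - cos(2 * pi * x / 24)))) {
    e1 <- envelope_1d(prof, 48)
    expect_true(all(e1 <= prof + 1e-12))
    e2 <- envelope_1d(e1, 48)
    expect_true(all(e2 <= e1 + 1e-12))   # re-application only tightens
  }
  # exact idempotence away from the profile ends on equal-height ridges
  prof <- 50 + 4 * (1 - cos(2 * pi * x / 24))
  e1 <- envelope_1d(prof, 48)
  e2 <- envelope_1d(e1, 48)
  expect_equal(e2[49:208], e1[49:208], tolerance = 1e-12)
})

test_that("upper envelope of a flat masked surface is the surface", {
  s <- oct_surface(matrix(30, 48, 48), nz = 64)
  b <- matrix(FALSE, 48, 48); b[9:40, 9:40] <- TRUE
  m <- oct_mask(b)
  e <- upper_envelope(s, m, envelope_config(l = 20, smooth_px = 5))
  expect_equal(e$heights[b], rep(30, sum(b)))
  expect_true(all(is.na(e$heights[!b])))
  expect_error(upper_envelope(s, oct_mask(matrix(FALSE, 48, 48))),
               "empty mask")
})

test_that("orthogonal passes rescue ridges crossed at shallow angles", {
  # ridges varying along x only: the x-pass sees full relief, the y-pass
  # runs along the ridge crests; the combined envelope sits at the tops
  nx <- 96
  hx <- 40 + 4 * (1 - cos(2 * pi * (1:nx) / 24))
  s <- oct_surface(matrix(hx, nx, nx), nz = 64)
  m <- oct_mask(matrix(TRUE, nx, nx))
  cfg <- envelope_config(l = 48, smooth_px = 1)
  e <- upper_envelope(s, m, cfg, smooth = FALSE)
  interior <- 25:72
  expect_lt(max(abs(e$heights[interior, interior] - 40)), 0.5)
})

test_that("combining passes commutes with transposition", {
  set.seed(31)
  h <- 40 + matrix(runif(64^2, 0, 6), 64, 64)
  b <- matrix(FALSE, 64, 64); b[9:56, 13:52] <- TRUE
  cfg <- envelope_config(l = 20, smooth_px = 5)
  e <- upper_envelope(oct_surface(h, 64), oct_mask(b), cfg)
  et <- upper_envelope(oct_surface(t(h), 64), oct_mask(t(b)), cfg)
  expect_equal(et$heights, t(e$heights), tolerance = 1e-12)
})

test_that("lower envelope mirrors the construction and brackets the surface", {
  nx <- 96
  u <- outer(1:nx, 1:nx, function(x, y) x + 0.6 * y)
  h <- 40 + 4 * (1 - cos(2 * pi * u / 24))
  s <- oct_surface(h, nz = 64)
  m <- oct_mask(matrix(TRUE, nx, nx))
  cfg <- envelope_config(l = 48, smooth_px = 9)
  eu <- upper_envelope(s, m, cfg)
  el <- lower_envelope(s, eu, m, cfg)
  expect_true(all(eu$heights <= s$heights + 1e-9))
  expect_true(all(s$heights <= el$heights + 1e-9))
  # envelope separation recovers the peak-to-valley ridge relief (8 here)
  interior <- 25:72
  sep <- el$heights[interior, interior] - eu$heights[interior, interior]
  expect_gt(mean(sep), 0.8 * 8)
  expect_lt(mean(sep), 1.2 * 8)

  # a flat surface collapses all three to the same plane
  sf <- oct_surface(matrix(25, 32, 32), nz = 64)
  mf <- oct_mask(matrix(TRUE, 32, 32))
  cf <- envelope_config(l = 10, smooth_px = 3)
  euf <- upper_envelope(sf, mf, cf)
  elf <- lower_envelope(sf, euf, mf, cf)
  expect_equal(euf$heights, sf$heights)
  expect_equal(elf$heights, sf$heights)
})

test_that("the envelope discards ridge-band information", {
  nx <- 128
  u <- outer(1:nx, 1:nx, function(x, y) 0.866 * x + 0.5 * y)
  set.seed(41)
  h <- 40 + 4 * (1 - cos(2 * pi * u / 24)) + matrix(rnorm(nx^2, 0, 0.3),
                                                    nx, nx)
  s <- oct_surface(h, nz = 128)
  m <- oct_mask(matrix(TRUE, nx, nx))
  eu <- upper_envelope(s, m, envelope_config(l = 48, smooth_px = 25))
  f0 <- 1 / 24
  crop <- 17:112
  ratio <- ridge_band_power(eu$heights[crop, crop], f0) /
    ridge_band_power(s$heights[crop, crop], f0)
  expect_lt(ratio, 0.05)
})
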