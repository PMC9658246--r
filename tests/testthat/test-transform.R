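# local helper: clamp without touching package internals
clamp_test <- function(x, lo, hi) pmin(pmax(x, lo), hi)

make_flat_setup <- function(nz = 64, h = 20) {
  ph <- generate_phantom(flat_slab_spec(dims = c(32, 32, nz), depth = h))
  s <- oct_surface(matrix(h, 32, 32), nz = nz)
  m <- oct_mask(matrix(TRUE, 32, 32))
  list(v = ph$volume, s = s, m = m)
}

test_that("flattening a flat surface is a pure uniform shift", {
  fx <- make_flat_setup()
  fl <- flatten_volume(fx$v, fx$s, fx$s, fx$m)   # E_S = S -> delta_S = 0
  expect_equal(fl$record$delta_s, 0)
  expect_true(all(fl$record$shift == 20))
  # boundary band moved to the top, vacated bottom zero-filled
  expect_equal(fl$volume$data[, , 1], fx$v$data[, , 21])
  expect_true(all(fl$volume$data[, , (64 - 19):64] == 0))
  expect_error(flatten_volume(fx$v, fx$s, fx$s,
                              oct_mask(matrix(FALSE, 32, 32))), "empty mask")
})

test_that("delta_S is exactly the masked maximum of S - E_S", {
  fx <- make_flat_setup()
  h <- fx$s$heights
  h[5, 7] <- 27.3                       # one deep ridge point
  s2 <- oct_surface(h, nz = 64)
  fl <- flatten_volume(fx$v, s2, fx$s, fx$m)
  expect_equal(fl$record$delta_s, 7.3)
  expect_equal(fl$record$delta_applied, 8)   # ceiling, snap = 1
  fl16 <- flatten_volume(fx$v, s2, fx$s, fx$m, snap = 16)
  expect_equal(fl16$record$delta_applied, 16)
})

test_that("unflattening inverts the recorded shifts exactly", {
  fx <- make_flat_setup()
  fl <- flatten_volume(fx$v, fx$s, fx$s, fx$m)
  det <- oct_surface(matrix(3.25, 32, 32), nz = 64)
  back <- unflatten_surface(det, fl$record)
  expect_equal(back$heights, matrix(23.25, 32, 32))
  # zero-shift record is the identity
  rec0 <- fl$record; rec0$shift[] <- 0L
  expect_equal(unflatten_surface(det, rec0)$heights, det$heights)
  expect_error(unflatten_surface(oct_surface(matrix(1, 4, 4), 64),
                                 fl$record), "mismatch")
})

test_that("flatten/unflatten round trip and flatness certificate hold on a
           ridged phantom", {
  ph <- generate_phantom(small_finger_spec())
  vc <- rolloff_compensate(ph$volume)
  s <- segment_fingerprint(vc)
  m <- refine_mask(raw_mask(vc, s, 20), 25)
  eup <- upper_envelope(s, m)
  fl <- flatten_volume(vc, s, eup, m, snap = 4)
  rec <- fl$record
  # round trip on a surface in the flattened frame: exact integer inverse
  det <- oct_surface(matrix(runif(128 * 128, 10, 60), 128, 128), nz = 128)
  back <- unflatten_surface(det, rec)
  ok <- m$bits & back$heights < 127     # away from the clamp boundary
  expect_lt(max(abs((back$heights - rec$shift - det$heights)[ok])), 1e-12)
  # the flattened outer surface sits within [0, delta + 1] of the top
  flat_pos <- (s$heights - rec$shift)[m$bits]
  expect_true(all(abs(flat_pos) <= rec$delta_applied + 1))
  expect_true(all(flat_pos <= 1))        # outer layer removed
  # out-of-mask lines are flagged
  expect_identical(rec$extrapolated, !m$bits)
})

test_that("2D projection maps the envelope bracket onto [0, 1]", {
  n <- 16
  m <- oct_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), n, n))
  eu <- oct_surface(matrix(20, n, n), nz = 64)
  el <- oct_surface(matrix(28, n, n), nz = 64)
  mk <- function(h) oct_surface(matrix(h, n, n), nz = 64)
  expect_true(all(project_2d(mk(20), eu, el, m)$pixels[m$bits] == 0))
  expect_true(all(project_2d(mk(28), eu, el, m)$pixels[m$bits] == 1))
  expect_true(all(project_2d(mk(24), eu, el, m)$pixels[m$bits] == 0.5))
  # clamping outside the bracket
  expect_true(all(project_2d(mk(35), eu, el, m)$pixels[m$bits] == 1))
  # degenerate separation -> featureless 0.5
  expect_true(all(project_2d(mk(20), eu, eu, m)$pixels[m$bits] == 0.5))
  # background is white
  fp <- project_2d(mk(24), eu, el, m)
  expect_true(all(fp$pixels[!m$bits] == 1))
  expect_equal(fp$ppi, 25400 / 20)
})

test_that("resampling to 500 ppi rescales the grid and metadata", {
  px <- matrix(runif(128 * 128), 128, 128)
  fp <- structure(list(pixels = px, ppi = 1270), class = "fingerprint_2d")
  out <- resample_fingerprint(fp, 500)
  expect_equal(out$ppi, 500)
  expect_equal(nrow(out$pixels), round(128 * 500 / 1270))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("ridge frequency of a synthetic pattern is recovered", {
  nx <- 128
  u <- outer(1:nx, 1:nx, function(x, y) 0.866 * x + 0.5 * y)
  img <- 0.5 + 0.4 * cos(2 * pi * u / 24)
  f <- ridge_frequency(img)
  expect_equal(f, 1 / 24, tolerance = 0.05)
})
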