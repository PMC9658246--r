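test_that("roll-off compensation leaves depth-constant volumes unchanged", {
  set.seed(3)
  slice <- matrix(round(runif(16 * 16, 20, 200)), 16, 16)
  v <- oct_volume(array(rep(slice, 16), c(16, 16, 16)), dtype = "uint8")
  out <- rolloff_compensate(v)
  expect_lt(max(abs(out$data - v$data)), 1 + 1e-9)
})

test_that("an exact linear decline is fully compensated", {
  nz <- 32
  base <- 150
  slope <- -1.5
  a <- array(0, c(8, 8, nz))
  for (z in seq_len(nz)) a[, , z] <- base + slope * (z - 1)
  v <- oct_volume(a, dtype = "uint8")
  out <- rolloff_compensate(v)
  A <- colMeans(matrix(out$data, 64, nz))
  expect_lt(max(A) - min(A), 1 + 1e-9)   # per-depth means constant to 1 LSB
})

test_that("compensation flattens the phantom's intensity roll-off", {
  ph <- generate_phantom(flat_slab_spec(dims = c(32, 32, 64),
                                        rolloff_slope = 2e-3,
                                        speckle_sigma = 0.2))
  fit_slope <- function(v) {
    A <- colMeans(matrix(v$data, 32 * 32, 64))
    z <- seq_len(64) - 1
    unname(stats::coef(stats::lm(A ~ z))[2])
  }
  s_before <- fit_slope(ph$volume)
  s_after <- fit_slope(rolloff_compensate(ph$volume))
  expect_gt(abs(s_before), 10 * abs(s_after))
})

test_that("pyramid halves dimensions and preserves constants and energy", {
  v <- oct_volume(array(37, c(64, 64, 64)), dtype = "uint8")
  p <- build_pyramid(v, 3)
  expect_equal(sapply(p$levels, function(l) dim(l$data)[1]),
               c(64, 32, 16, 8))
  for (l in p$levels) expect_true(all(l$data == 37))

  # a single bright voxel's energy lands in its one covering parent
  a <- array(0, c(8, 8, 8)); a[3, 5, 2] <- 240
  p1 <- build_pyramid(oct_volume(a), 1)
  expect_equal(sum(p1$levels[[2]]$data), 240 / 8, tolerance = 1e-9)
  expect_equal(sum(p1$levels[[2]]$data > 0), 1)

  expect_error(build_pyramid(oct_volume(array(0, c(12, 12, 12))), 3),
               "divisible")
})

test_that("upsampling a constant field is exactly constant (no clusters)", {
  u <- octseg:::upsample2(array(5.5, c(8, 8, 8)))
  expect_equal(dim(u), c(16, 16, 16))
  expect_equal(max(u) - min(u), 0)
})

test_that("contrast enhancement is the per-voxel geometric mean", {
  # constant pyramid: every level keeps its value (sqrt(c * c) = c)
  v <- oct_volume(array(64, c(16, 16, 16)), dtype = "uint8")
  p <- contrast_enhance(build_pyramid(v, 2))
  for (l in p$levels) expect_true(all(l$data == 64))

  # a coarse level at the dtype max leaves the finer level unchanged up to
  # the square-root compression
  a <- array(255, c(16, 16, 16))
  a[1:8, , ] <- 100
  p2 <- build_pyramid(oct_volume(a, dtype = "uint8"), 1)
  p2$levels[[2]]$data[] <- 255
  out <- contrast_enhance(p2)$levels[[1]]$data
  expect_true(all(out[12:16, , ] == 255))
  expect_true(all(out[1:5, , ] == round(sqrt(100 * 255))))
})

test_that("enhancement preserves the argmax of a single dominant layer", {
  # junction brightness barely above tissue: one dominant bright layer
  ph <- generate_phantom(flat_slab_spec(dims = c(32, 32, 64), depth = 30,
                                        speckle_sigma = 0.2,
                                        brightness = c(surface = 230,
                                                       junction = 61,
                                                       tissue = 60,
                                                       background = 8)))
  before <- apply(ph$volume$data, c(1, 2), which.max)
  p <- contrast_enhance(build_pyramid(ph$volume, 2))
  after <- apply(p$levels[[1]]$data, c(1, 2), which.max)
  # lines whose raw argmax already sat on the layer stay put...
  on_layer <- abs(before - 31) <= 2
  expect_gt(mean(on_layer), 0.99)
  expect_lt(max(abs((after - before)[on_layer])), 1 + 1e-9)
  # ...and the handful of speckle-displaced lines are pulled back to it
  expect_true(all(abs(after - 31) <= 2))
})
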