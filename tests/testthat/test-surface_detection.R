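test_that("detection finds a flat boundary with every kernel", {
  ph <- generate_phantom(flat_slab_spec(depth = 40))
  rs <- detect_surface(ph$volume, full_region(64, 64, 64), c(8, 12, 16))
  for (L in c("8", "12", "16")) {
    expect_true(all(!is.na(rs$pos[[L]])))
    expect_lt(max(abs(rs$pos[[L]] - 40)), 1)
    expect_true(all(rs$wt[[L]] > 0))
  }
})

test_that("an all-zero volume yields only holes", {
  v <- oct_volume(array(0, c(16, 16, 32)), dtype = "uint8")
  rs <- detect_surface(v, full_region(16, 16, 32), c(4, 8))
  expect_true(all(is.na(rs$pos[["4"]])))
  expect_true(all(is.na(rs$pos[["8"]])))
  expect_error(detect_surface(v, full_region(16, 16, 32), integer(0)),
               "empty kernel set")
})

test_that("pure noise produces mostly holes or weak responses", {
  ph <- generate_phantom(flat_slab_spec(depth = 40, speckle_sigma = 0.3))
  rs_slab <- detect_surface(ph$volume, full_region(64, 64, 64), 8)
  slab_median <- stats::median(rs_slab$wt[["8"]])
  set.seed(99)
  noise <- oct_volume(array(round(runif(64^3, 0, 255)), c(64, 64, 64)),
                      dtype = "uint8")
  rs <- detect_surface(noise, full_region(64, 64, 64), 8)
  weak <- is.na(rs$pos[["8"]]) | rs$wt[["8"]] < slab_median
  expect_gt(mean(weak), 0.5)
})

test_that("kernel selection minimizes the neighborhood weighted deviation", {
  # hand-built result set: kernel 4 flat at 40, kernel 8 alternating 40 +- 5
  nx <- ny <- 12
  alt <- matrix(40 + 5 * (-1)^(outer(1:nx, 1:ny, "+")), nx, ny)
  rs <- structure(list(
    Ls = c(4L, 8L),
    pos = list("4" = matrix(40, nx, ny), "8" = alt),
    wt = list("4" = matrix(1, nx, ny), "8" = matrix(1, nx, ny)),
    dims = c(nx, ny), nz = 64L), class = "result_set")
  sel <- select_kernel_per_line(rs, r_var = 2)
  expect_true(all(sel$kernel == 4))
  expect_true(all(sel$heights == 40))

  # direct weighted-sd oracle agrees on an interior neighborhood
  nb <- as.vector(alt[3:7, 3:7])
  expect_gt(weighted_sd(nb, rep(1, 25)), 0)
  expect_equal(weighted_sd(rep(40, 25), rep(1, 25)), 0)
})

test_that("ties between equal kernels go to the smaller size", {
  nx <- ny <- 8
  rs <- structure(list(
    Ls = c(4L, 8L),
    pos = list("4" = matrix(40, nx, ny), "8" = matrix(40, nx, ny)),
    wt = list("4" = matrix(1, nx, ny), "8" = matrix(1, nx, ny)),
    dims = c(nx, ny), nz = 64L), class = "result_set")
  sel <- select_kernel_per_line(rs, r_var = 1)
  expect_true(all(sel$kernel == 4))
})

test_that("isolated spikes are demoted to holes and re-interpolated", {
  nx <- ny <- 12
  p <- matrix(40, nx, ny); p[6, 6] <- 20      # lone candidate far off
  rs <- structure(list(
    Ls = 8L, pos = list("8" = p), wt = list("8" = matrix(1, nx, ny)),
    dims = c(nx, ny), nz = 64L), class = "result_set")
  sel <- select_kernel_per_line(rs, r_var = 2)
  expect_true(is.na(sel$heights[6, 6]))
  filled <- fill_holes(sel)
  expect_equal(filled$heights[6, 6], 40)
})

test_that("region narrowing sizes the band from the weighted median kernel", {
  h <- matrix(40, 16, 16)
  s <- oct_surface(h, nz = 256)
  sel <- oct_surface(h, nz = 256)
  sel$kernel <- matrix(8L, 16, 16)
  sel$weight <- matrix(1, 16, 16)
  r <- narrow_region(s, sel, f_w = 1.5, scale = 1)
  expect_equal(r$median_kernel, 8)
  expect_true(all(r$lo == floor(40 - 12)))   # half-width f_w * 8 = 12
  expect_true(all(r$hi == ceiling(40 + 12)))

  # surface near the top: lower bound clips to 0
  s0 <- oct_surface(matrix(4, 16, 16), nz = 256)
  r0 <- narrow_region(s0, sel, f_w = 1.5, scale = 1)
  expect_true(all(r0$lo == 0))

  # equal-weight tie between kernel sizes resolves to the smaller one
  sel$kernel[1:8, ] <- 8L
  sel$kernel[9:16, ] <- 16L
  r2 <- narrow_region(s, sel, f_w = 1.5, scale = 1)
  expect_equal(r2$median_kernel, 8)
})

test_that("hole filling interpolates from the perimeter", {
  h <- matrix(40, 10, 10); h[5, 5] <- NA
  s <- fill_holes(oct_surface(h, nz = 64))
  expect_equal(s$heights[5, 5], 40)

  # on a planar gradient the fill is close to the plane
  hp <- outer(1:10, 1:10, function(x, y) 10 + 0.7 * x + 0.4 * y)
  hh <- hp; hh[4, 6] <- NA
  sp <- fill_holes(oct_surface(hh, nz = 64))
  expect_lt(abs(sp$heights[4, 6] - hp[4, 6]), 0.5)

  # a 3x3 hole block collapses within 3 passes
  hb <- matrix(40, 12, 12); hb[5:7, 5:7] <- NA
  expect_silent(fill_holes(oct_surface(hb, nz = 64), max_iters = 3))

  expect_error(fill_holes(oct_surface(matrix(NA_real_, 4, 4), nz = 8)),
               "no defined heights")
})

test_that("segmentation recovers a noiseless flat slab almost exactly", {
  ph <- generate_phantom(flat_slab_spec(depth = 20))
  s <- segment_fingerprint(rolloff_compensate(ph$volume))
  expect_lt(surface_rmse(s, ph$truth$outer), 0.5)
  expect_false(anyNA(s$heights))
})

test_that("segmentation is deterministic and accurate on a ridged finger", {
  ph <- generate_phantom(small_finger_spec())
  vc <- rolloff_compensate(ph$volume)
  s1 <- segment_fingerprint(vc)
  s2 <- segment_fingerprint(vc)
  expect_identical(s1$heights, s2$heights)
  expect_lt(surface_rmse(s1, ph$truth$outer, ph$truth$contact), 1.5)
  expect_true(!is.null(s1$log))
  expect_equal(s1$log$N, 2)   # 128-cube default pyramid depth
})

test_that("an unsuited kernel size barely disturbs the result", {
  ph <- generate_phantom(small_finger_spec())
  vc <- rolloff_compensate(ph$volume)
  base <- surface_rmse(segment_fingerprint(vc), ph$truth$outer,
                       ph$truth$contact)
  cfg <- detection_config(L_N = c(4, 6, 8, 12, 16, 48))  # 48 >> band width
  with_bad <- surface_rmse(segment_fingerprint(vc, cfg), ph$truth$outer,
                           ph$truth$contact)
  expect_lt(abs(with_bad - base), 0.1 * base + 0.05)
})

test_that("masked segmentation skips unmasked lines", {
  ph <- generate_phantom(flat_slab_spec(depth = 20))
  b <- matrix(FALSE, 64, 64); b[17:48, 17:48] <- TRUE
  s <- segment_fingerprint(rolloff_compensate(ph$volume),
                           m = oct_mask(b))
  expect_true(all(!is.na(s$heights[b])))
  expect_true(all(is.na(s$heights[!b])))
})

test_that("config files round-trip through YAML and reject unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("f_w: 2.0", "L_N: [4, 8]", "r_var: 3"), tmp)
  cfg <- read_detection_config(tmp)
  expect_equal(cfg$f_w, 2.0)
  expect_equal(cfg$L_N, c(4L, 8L))
  expect_equal(cfg$r_var, 3L)
  writeLines("bogus_key: 1", tmp)
  expect_error(read_detection_config(tmp), "unknown")
  expect_error(detection_config(f_w = 0.5), "f_w")
  expect_error(detection_config(L_N = c(3, 4)), "even")
})
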