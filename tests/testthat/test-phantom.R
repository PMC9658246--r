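test_that("generation is deterministic given the spec", {
  sp <- small_finger_spec(seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$outer$heights, b$truth$outer$heights)
  sp2 <- small_finger_spec(seed = 10)
  expect_false(identical(generate_phantom(sp2)$volume$data, a$volume$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(generate_phantom(flat_slab_spec(dims = c(16, 16, 16), depth = 4,
                                            epidermis_depth = 6)))
  expect_identical(runif(3), x1)
})

test_that("noiseless flat slab has its per-line argmax exactly at the truth", {
  ph <- generate_phantom(flat_slab_spec(depth = 20))
  am <- apply(ph$volume$data, c(1, 2), which.max) - 1
  expect_true(all(am == 20))
  expect_true(all(ph$truth$outer$heights == 20))
  expect_true(all(ph$truth$inner$heights > ph$truth$outer$heights))
})

test_that("the roll-off factor shows up in the per-depth mean profile", {
  a <- 2e-3
  sp0 <- flat_slab_spec(dims = c(32, 32, 64), speckle_sigma = 0)
  sp1 <- flat_slab_spec(dims = c(32, 32, 64), speckle_sigma = 0,
                        rolloff_slope = a)
  A0 <- colMeans(matrix(generate_phantom(sp0)$volume$data, 32 * 32, 64))
  A1 <- colMeans(matrix(generate_phantom(sp1)$volume$data, 32 * 32, 64))
  keep <- A0 > 30                        # depths with real signal
  z <- (seq_len(64) - 1)[keep]
  ratio <- A1[keep] / A0[keep]           # should follow 1 - a z
  fit <- unname(stats::coef(stats::lm(ratio ~ z))[2])
  expect_equal(fit, -a, tolerance = 0.1)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(ridge_depth = 30, epidermis_depth = 20),
               "ridge_depth")
  expect_error(phantom_spec(brightness = c(surface = 10, junction = 140,
                                           tissue = 60, background = 8)),
               "ordering")
  expect_error(phantom_spec(dims = c(4, 4, 4)), "dims")
})

test_that("presets are valid and scarring leaves the junction untouched", {
  specs <- phantom_presets()
  expect_true(all(c("flat-slab", "clean-finger-256", "noisy-finger-256",
                    "scarred-finger", "off-center-tilted") %in% names(specs)))
  for (sp in specs) expect_s3_class(octseg:::validate_phantom_spec(sp),
                                    "phantom_spec")
  fs <- phantom_preset("flat-slab")
  expect_true(is.infinite(fs$curvature_radius))
  expect_equal(fs$ridge_depth, 0)
  expect_equal(fs$speckle_sigma, 0)

  clean <- phantom_preset("clean-finger-256")
  scar <- phantom_preset("scarred-finger")
  clean$dims <- scar$dims <- c(64, 64, 128)
  clean$contact_radius <- scar$contact_radius <- 28
  a <- generate_phantom(clean); b <- generate_phantom(scar)
  expect_identical(b$truth$inner$heights, a$truth$inner$heights)
  expect_true(any(b$truth$outer$heights != a$truth$outer$heights,
                  na.rm = TRUE))
  expect_true(all((b$truth$outer$heights > a$truth$outer$heights)[
    b$truth$scar_area & b$truth$contact$bits]))
  expect_error(phantom_preset("no-such"), "unknown preset")
})

test_that("spec serialization round-trips through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  sp <- phantom_preset("scarred-finger")
  out <- unclass(sp)
  out$brightness <- as.list(out$brightness)   # keep names in JSON
  jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  back <- jsonlite::fromJSON(tmp)
  back$brightness <- unlist(back$brightness)
  sp2 <- do.call(phantom_spec, back)
  expect_identical(generate_phantom(sp2)$volume$data,
                   generate_phantom(sp)$volume$data)
})

test_that("surface_rmse measures inside the mask", {
  t1 <- oct_surface(matrix(10, 8, 8), nz = 64)
  t2 <- oct_surface(matrix(c(10, 13), 8, 8), nz = 64)
  expect_equal(surface_rmse(t2, t1), sqrt(mean(c(0, 9))))
  m <- oct_mask(matrix(rep(c(TRUE, FALSE), 32), 8, 8))
  expect_equal(surface_rmse(t2, t1, m), 0)
})
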