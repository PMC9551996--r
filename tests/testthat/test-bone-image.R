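test_that("Gaussian smoothing preserves constants and conserves mass", {
  f <- grayscale_field(matrix(7.5, 40, 40), 0.082, "raw")
  s <- smooth_field(f, sigma = 1.2, support = 2.0)
  expect_equal(s$values, f$values, tolerance = 1e-12)

  set.seed(3)
  g <- grayscale_field(matrix(runif(40 * 40), 40, 40), 0.082, "raw")
  sg <- smooth_field(g, sigma = 1.2, support = 2.0)
  expect_lt(abs(sum(sg$values) - sum(g$values)) / sum(g$values), 1e-6)
})

test_that("smoothing a delta keeps its mass within the truncation radius", {
  v <- matrix(0, 21, 21)
  v[11, 11] <- 1
  s <- smooth_field(grayscale_field(v, 0.082, "raw"), 1.2, 2.0)
  expect_lt(abs(sum(s$values) - 1), 1e-6)
  # support = 2.0 sigma -> kernel radius floor(2.4) = 2 pixels
  inside <- s$values[9:13, 9:13]
  expect_equal(sum(inside), 1, tolerance = 1e-12)
  # maximum stays at the delta and is strictly smaller than the input peak
  expect_equal(which.max(s$values), 11L + 10L * 21L)
  expect_lt(max(s$values), 1)
})

test_that("smoothing rejects bad parameters and wrong tags", {
  f <- grayscale_field(matrix(1, 5, 5), 0.1, "raw")
  expect_error(smooth_field(f, sigma = -1), "sigma")
  expect_error(smooth_field(f, support = 0), "must be > 0")
  fv <- grayscale_field(matrix(1, 5, 5), 0.1, "vbmd")
  expect_error(smooth_field(fv), "raw")
})

test_that("max projection matches its definition and degenerate cases", {
  set.seed(4)
  a <- grayscale_field(matrix(runif(25), 5, 5), 0.1, "raw")
  b <- grayscale_field(matrix(runif(25), 5, 5), 0.1, "raw")
  expect_equal(max_projection(list(a, b), k = 2, seed = 1)$values,
               pmax(a$values, b$values))
  expect_equal(max_projection(list(a, b), k = 1, seed = 7)$values,
               max_projection(list(a, b), k = 1, seed = 7)$values)
  same <- replicate(15, a, simplify = FALSE)
  expect_equal(max_projection(same, k = 15, seed = 2)$values, a$values)
  expect_error(max_projection(list(a), k = 2), "at least")
})

test_that("max projection is monotone non-decreasing in k per pixel", {
  set.seed(5)
  slices <- lapply(1:6, function(i) {
    grayscale_field(matrix(runif(36), 6, 6), 0.1, "raw")
  })
  # with a fixed seed the first k selections are nested
  p2 <- max_projection(slices, k = 2, seed = 9)$values
  p4 <- max_projection(slices, k = 4, seed = 9)$values
  expect_true(all(p4 >= p2))
})

test_that("vBMD calibration is affine and clamps negatives", {
  f <- grayscale_field(matrix(c(100, -30, 0, 50), 2, 2), 0.1, "raw")
  v <- calibrate_vbmd(f, slope = 0.5, intercept = 10)
  expect_equal(v$values[1, 1], 60)
  expect_equal(v$semantics_tag, "vbmd")
  id <- calibrate_vbmd(f, slope = 1, intercept = 0)
  expect_equal(id$values, pmax(f$values, 0))
  # clamp count equals the count of pixels with slope*v + intercept < 0
  g <- grayscale_field(matrix(seq(-50, 49, length.out = 100), 10, 10),
                       0.1, "raw")
  cal <- calibrate_vbmd(g, slope = 2, intercept = -10.3)
  expect_equal(sum(cal$values == 0), sum(2 * g$values - 10.3 < 0))
})

test_that("ash density conversion follows the printed affine law", {
  z <- grayscale_field(matrix(0, 2, 2), 0.1, "vbmd")
  expect_equal(vbmd_to_ash(z)$values[1, 1], 0.079)
  th <- grayscale_field(matrix(1000, 2, 2), 0.1, "vbmd")
  expect_equal(vbmd_to_ash(th)$values[1, 1], 877.079)
  set.seed(6)
  a <- grayscale_field(matrix(runif(9, 0, 1200), 3, 3), 0.1, "vbmd")
  b <- grayscale_field(matrix(runif(9, 0, 1200), 3, 3), 0.1, "vbmd")
  expect_equal(vbmd_to_ash(a)$values - vbmd_to_ash(b)$values,
               0.877 * (a$values - b$values), tolerance = 1e-12)
})

test_that("density-modulus law applies the power law with a floor", {
  z <- grayscale_field(matrix(0, 3, 3), 0.1, "ash_density")
  m0 <- ash_to_modulus(z)
  expect_true(all(m0$values == 1e-6 * 10500))
  one <- grayscale_field(matrix(1000, 2, 2), 0.1, "ash_density")
  expect_equal(ash_to_modulus(one)$values[1, 1], 10500) # 1 g/cm^3
  r <- grayscale_field(matrix(c(400, 800), 1, 2), 0.1, "ash_density")
  m <- ash_to_modulus(r)
  expect_equal(m$values[1, 2] / m$values[1, 1], 2^2.29, tolerance = 1e-12)
  expect_error(ash_to_modulus(one, coeff = -1), "coeff")
})

test_that("semantics tags only advance along the chain", {
  raw <- grayscale_field(matrix(1, 2, 2), 0.1, "raw")
  expect_error(vbmd_to_ash(raw), "vbmd")
  expect_error(ash_to_modulus(calibrate_vbmd(raw)), "ash_density")
})

test_that("synthetic slices hit the requested solid fraction and are seeded", {
  p <- synth_bone_params(size_mm = 8, pixel_pitch = 0.1,
                         target_solid_fraction = 0.3, n_slices = 4,
                         seed = 12)
  s1 <- synth_slices(p)
  s2 <- synth_slices(p)
  expect_identical(s1[[2]]$values, s2[[2]]$values)
  proj <- Reduce(pmax, lapply(s1, function(f) f$values))
  frac <- mean(proj > 0)
  expect_gte(frac, 0.29)
  expect_lte(frac, 0.31)
  expect_error(synth_bone_params(target_solid_fraction = 1.2), "fraction")
})

test_that("correlation-length anisotropy propagates to the stiffness", {
  p <- synth_bone_params(size_mm = 12, pixel_pitch = 0.2,
                         correlation_length_x = 1.8,
                         correlation_length_y = 0.6,
                         n_slices = 1, seed = 5)
  bt <- bone_target_model(p, projection_k = 1)
  cm <- homogenize(bt$model)
  expect_gt(abs(cm$c11 - cm$c22) / max(cm$c11, cm$c22), 0.05)
})

test_that("the full image-to-model chain is deterministic under seed", {
  p <- synth_bone_params(size_mm = 6, pixel_pitch = 0.2, n_slices = 3,
                         seed = 77)
  a <- bone_target_model(p, projection_k = 3)
  b <- bone_target_model(p, projection_k = 3)
  expect_identical(a$field$values, b$field$values)
  expect_equal(a$field$semantics_tag, "modulus")
})
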