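test_that("encode/decode is a bijection on the thickness lattice", {
  d0 <- scaffold_design(rep(0.2, 36))
  expect_true(all(encode_design(d0) == 0.2))
  for (i in 1:200) {
    d <- random_design(seed = i)
    rt <- decode_design(encode_design(d))
    expect_identical(scafmatch:::design_vector(rt),
                     scafmatch:::design_vector(d))
  }
})

test_that("changing one matrix entry changes exactly one thickness", {
  d <- random_design(seed = 42)
  m <- encode_design(d)
  m2 <- m
  m2[3, 5] <- if (m[3, 5] == 0.2) 0.6 else 0.2
  v1 <- scafmatch:::design_vector(decode_design(m))
  v2 <- scafmatch:::design_vector(decode_design(m2))
  expect_equal(sum(v1 != v2), 1)
})

test_that("thickness validation is strict", {
  expect_error(scaffold_design(rep(0.3, 36)), "no snapping")
  expect_error(scaffold_design(rep(0.2, 35)), "36")
  expect_error(decode_design(matrix(0.25, 6, 6)), "no snapping")
})

test_that("rasterized solid fractions match the frame-lattice area formula", {
  # interior hole per cell is (6 - 2 t)^2; solid fraction 1 - 9 (6-2t)^2/18^2
  d6 <- scaffold_design(rep(0.6, 36))
  mask6 <- rasterize_mask(d6, pixel_size = 0.1)
  expect_equal(dim(mask6), c(180L, 180L))
  expect_equal(mean(mask6), 1 - 9 * 4.8^2 / 18^2) # 0.36, pixel-exact
  d2 <- scaffold_design(rep(0.2, 36))
  expect_equal(mean(rasterize_mask(d2, 0.1)), 1 - 9 * 5.6^2 / 18^2)
  # coarse raster remains pixel-exact because 0.2 mm divides every width
  expect_equal(mean(rasterize_mask(d6, 0.2)), 1 - 9 * 4.8^2 / 18^2)
  expect_error(rasterize_mask(d6, 0.07), "integer multiple")
})

test_that("every design rasterizes to one connected component", {
  for (i in c(3, 17, 99)) {
    mask <- rasterize_mask(random_design(seed = i), pixel_size = 0.2)
    expect_equal(n_components(mask), 1)
  }
})

test_that("porosity values and monotonicity", {
  expect_equal(porosity(scaffold_design(rep(0.6, 36))), 0.64)
  expect_equal(porosity(scaffold_design(rep(0.2, 36))), 9 * 5.6^2 / 18^2)
  d <- random_design(seed = 7)
  v <- scafmatch:::design_vector(d)
  i <- which(v == 0.2)[1]
  v2 <- v
  v2[i] <- 0.4
  expect_lt(porosity(scaffold_design(v2)), porosity(d))
})

test_that("abutting walls of neighboring cells stack across the boundary", {
  # left column thick right walls + middle column thick left walls
  v <- rep(0.2, 36)
  d <- scaffold_design(v)
  m <- encode_design(d)
  m[1, 2 * 1] <- 0.2 # keep
  # make cell (1,1) right wall 0.6 and cell (1,2) left wall 0.4
  m[2, 2] <- 0.6
  m[1, 3] <- 0.4
  dd <- decode_design(m)
  mask <- rasterize_mask(dd, pixel_size = 0.1)
  # across x = 6 mm the solid band spans 0.6 + 0.4 = 1.0 mm (10 px):
  # columns 55..60 (right wall) plus 61..64 (left wall), mid-height row
  expect_true(all(mask[30, 55:64]))
  expect_false(mask[30, 54])
  expect_false(mask[30, 65])
})

test_that("random designs are seeded and roughly uniform over levels", {
  expect_identical(scafmatch:::design_vector(random_design(seed = 5)),
                   scafmatch:::design_vector(random_design(seed = 5)))
  set.seed(1)
  counts <- c(`0.2` = 0, `0.4` = 0, `0.6` = 0)
  n <- 2000
  for (i in 1:n) {
    v <- scafmatch:::design_vector(random_design())
    counts <- counts + table(factor(v, levels = c(0.2, 0.4, 0.6)))
  }
  freq <- counts / (36 * n)
  expect_true(all(freq > 0.32 & freq < 0.35))
})

test_that("random_designs returns n distinct seeded designs", {
  ds <- random_designs(50, seed = 9)
  keys <- vapply(ds, scafmatch:::design_key, character(1))
  expect_equal(length(unique(keys)), 50)
  ds2 <- random_designs(50, seed = 9)
  expect_identical(keys, vapply(ds2, scafmatch:::design_key, character(1)))
})

test_that("the periodic enumeration covers the 81 conventional designs", {
  pd <- enumerate_periodic()
  expect_equal(length(pd), 81)
  keys <- vapply(pd, scafmatch:::design_key, character(1))
  expect_equal(length(unique(keys)), 81)
  # every design has 9 identical 2x2 blocks in its matrix encoding
  for (d in pd[c(1, 40, 81)]) {
    m <- encode_design(d)
    blocks <- lapply(0:8, function(b) {
      r <- (b %/% 3) * 2
      cc <- (b %% 3) * 2
      m[r + 1:2, cc + 1:2]
    })
    expect_true(all(vapply(blocks, function(bl) all(bl == blocks[[1]]),
                           logical(1))))
  }
  all04 <- vapply(pd, function(d) all(d$thickness == 0.4), logical(1))
  expect_equal(sum(all04), 1)
})

test_that("stiffness increases from the thinnest to the thickest lattice", {
  c2 <- homogenize_design(scaffold_design(rep(0.2, 36)), pixel_size = 0.2)
  c6 <- homogenize_design(scaffold_design(rep(0.6, 36)), pixel_size = 0.2)
  expect_gt(c6$c11, c2$c11)
  expect_gt(c6$c33, c2$c33)
})

test_that("design serialization round-trips", {
  d <- random_design(seed = 123)
  path <- tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_identical(scafmatch:::design_vector(d2),
                   scafmatch:::design_vector(d))
  cm <- elasticity_matrix(100, 20, 1, 90, 2, 30)
  pe <- tempfile(fileext = ".json")
  write_elasticity(cm, pe)
  expect_equal(as.matrix(read_elasticity(pe)), as.matrix(cm))
})
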