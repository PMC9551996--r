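test_that("homogeneous plate reproduces the closed-form stiffness", {
  m <- plane_stress_model(matrix(113800, 30, 30), 0.34, 0.2)
  cm <- homogenize(m)
  ref <- plate_closed_form(113800, 0.34)
  expect_lt(rel_diff(cm$c11, ref[1, 1]), 1e-3)
  expect_lt(rel_diff(cm$c12, ref[1, 2]), 1e-3)
  expect_lt(rel_diff(cm$c22, ref[2, 2]), 1e-3)
  expect_lt(rel_diff(cm$c33, ref[3, 3]), 1e-3)
  expect_lt(abs(cm$c13) / ref[1, 1], 1e-9)
  expect_lt(abs(cm$c23) / ref[1, 1], 1e-9)
  # the affine-boundary FE solution of a homogeneous plate is exact
  expect_lt(rel_diff(cm$c11, 128674.8), 1e-5)
})

test_that("solve_case handles canonical cases and rejects mixed strains", {
  m <- plane_stress_model(matrix(1000, 8, 8), 0.3, 0.5)
  s <- solve_case(m, load_case(eps_x = -0.1))
  expect_equal(s$sigma_x / (-0.1), 1000 / (1 - 0.09), tolerance = 1e-9)
  expect_error(load_case(eps_x = 0.1, eps_y = 0.1), "exactly one")
  expect_error(load_case(), "exactly one")
})

test_that("average stress is linear in the material", {
  set.seed(10)
  e <- matrix(exp(rnorm(100, log(5000), 1)), 10, 10)
  m1 <- plane_stress_model(e, 0.3, 0.2)
  m2 <- plane_stress_model(2 * e, 0.3, 0.2)
  s1 <- solve_case(m1, load_case(eps_x = -0.1))
  s2 <- solve_case(m2, load_case(eps_x = -0.1))
  expect_equal(s2$sigma_x, 2 * s1$sigma_x, tolerance = 1e-9)
  expect_equal(s2$tau_xy, 2 * s1$tau_xy, tolerance = 1e-9)
  c1 <- homogenize(m1)
  c2 <- homogenize(m2)
  expect_equal(as.matrix(c2), 2 * as.matrix(c1), tolerance = 1e-9)
})

test_that("the redundant c21 measurement matches c12 on random grids", {
  set.seed(11)
  for (rep in 1:3) {
    e <- matrix(exp(rnorm(144, log(2000), 1.5)), 12, 12)
    cm <- homogenize(plane_stress_model(e, 0.34, 0.1))
    expect_lt(abs(cm$c12 - cm$c21) / max(abs(cm$c12), abs(cm$c21)), 1e-6)
  }
})

test_that("the homogenized matrix is invariant to the strain magnitude", {
  set.seed(12)
  e <- matrix(exp(rnorm(64, log(1000), 1)), 8, 8)
  m <- plane_stress_model(e, 0.3, 0.25)
  a <- homogenize(m, magnitude = 0.1)
  b <- homogenize(m, magnitude = 0.01)
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-9)
})

test_that("rotating the grid by 90 degrees swaps c11 and c22, keeps c33", {
  set.seed(13)
  e <- matrix(exp(rnorm(225, log(3000), 1.2)), 15, 15)
  m <- plane_stress_model(e, 0.3, 0.2)
  # rotate the grid by 90 degrees: rows (y) become columns (x)
  er <- t(e)[, rev(seq_len(nrow(e)))]
  mr <- plane_stress_model(er, 0.3, 0.2)
  a <- homogenize(m)
  b <- homogenize(mr)
  expect_equal(b$c11, a$c22, tolerance = 1e-6)
  expect_equal(b$c22, a$c11, tolerance = 1e-6)
  expect_equal(b$c33, a$c33, tolerance = 1e-6)
})

test_that("porous stiffness is bounded by the fully solid plate", {
  set.seed(14)
  e <- matrix(113800, 12, 12)
  holes <- sample(144, 50)
  e[holes] <- 113800 * 1e-6
  porous <- homogenize(plane_stress_model(e, 0.34, 0.2))
  solid <- homogenize(plane_stress_model(matrix(113800, 12, 12), 0.34, 0.2))
  expect_lt(porous$c11, solid$c11)
  expect_lt(porous$c33, solid$c33)
})

test_that("model validation rejects non-physical inputs", {
  expect_error(plane_stress_model(matrix(0, 3, 3), 0.3, 0.1), "> 0")
  expect_error(plane_stress_model(matrix(1, 3, 3), 0.6, 0.1), "poisson")
  expect_error(plane_stress_model(matrix(1, 3, 3), 0.3, -1), "element_size")
  m <- plane_stress_model(matrix(1, 3, 3), 0.3, 0.1)
  expect_error(homogenize(m, magnitude = 0), "magnitude")
})

test_that("a zero-strain state produces zero average stress", {
  m <- plane_stress_model(matrix(1000, 6, 6), 0.3, 0.1)
  st <- scafmatch:::solve_cases_internal(
    m, list(structure(list(eps_x = 0, eps_y = 0, gamma_xy = 0),
                      class = "load_case")))
  expect_equal(st[[1]]$sigma_x, 0)
  expect_equal(st[[1]]$sigma_y, 0)
  expect_equal(st[[1]]$tau_xy, 0)
})

test_that("a reused grid solver reproduces the standalone result", {
  set.seed(15)
  gs <- grid_solver(10, 10, 0.34, 0.2)
  for (i in 1:2) {
    e <- matrix(exp(rnorm(100, log(1000), 1)), 10, 10)
    m <- plane_stress_model(e, 0.34, 0.2)
    expect_equal(as.matrix(homogenize(m, solver = gs)),
                 as.matrix(homogenize(m)), tolerance = 1e-12)
  }
})
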