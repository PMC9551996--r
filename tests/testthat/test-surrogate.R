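test_that("model building is deterministic under the spec seed", {
  sp <- cnn_spec(seed = 11)
  m1 <- cnn_build(sp)
  m2 <- cnn_build(sp)
  X <- matrix(runif(5 * 36), 5, 36)
  expect_identical(cnn_forward(m1, X)$out, cnn_forward(m2, X)$out)
  m3 <- cnn_build(cnn_spec(seed = 12))
  expect_false(identical(cnn_forward(m1, X)$out, cnn_forward(m3, X)$out))
})

test_that("both output heads propagate a 6x6 input with the right shape", {
  X <- matrix(runif(3 * 36), 3, 36)
  mc <- cnn_build(cnn_spec(head = "constants", seed = 1))
  expect_equal(dim(cnn_forward(mc, X)$out), c(3L, 6L))
  mo <- cnn_build(cnn_spec(head = "objective", seed = 1))
  expect_equal(dim(cnn_forward(mo, X)$out), c(3L, 1L))
  # a single-sample batch also propagates
  expect_equal(dim(cnn_forward(mc, X[1, , drop = FALSE])$out), c(1L, 6L))
})

test_that("backpropagation matches numerical gradients", {
  m <- cnn_build(cnn_spec(conv_widths = c(3, 4, 5), fc_widths = c(6, 5),
                          dropout = 0, seed = 42))
  set.seed(7)
  X <- matrix(runif(4 * 36), 4, 36)
  Y <- matrix(runif(4 * 6), 4, 6)
  fw <- cnn_forward(m, X)
  dout <- sign(fw$out - Y) / length(Y)
  g <- scafmatch:::cnn_backward(m, fw, dout)
  lossfn <- function(mm) mean(abs(cnn_forward(mm, X)$out - Y))
  eps <- 1e-6
  probes <- list(
    list(get = function(mm) mm$params$conv2$W[[5]],
         set = function(mm, v) { mm$params$conv2$W[[5]][] <- v; mm },
         grad = g$conv2$W[[5]]),
    list(get = function(mm) mm$params$fc1$W,
         set = function(mm, v) { mm$params$fc1$W[] <- v; mm },
         grad = g$fc1$W),
    list(get = function(mm) mm$params$conv1$b,
         set = function(mm, v) { mm$params$conv1$b <- v; mm },
         grad = g$conv1$b)
  )
  set.seed(8)
  for (pr in probes) {
    v <- pr$get(m)
    for (k in 1:5) {
      i <- sample(length(v), 1)
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      num <- (lossfn(pr$set(m, vp)) - lossfn(pr$set(m, vm))) / (2 * eps)
      expect_equal(num, pr$grad[i], tolerance = 1e-4)
    }
  }
})

test_that("training memorizes a small dataset and is seed-reproducible", {
  set.seed(30)
  designs <- lapply(1:50, function(i) encode_design(random_design()))
  ct <- elasticity_matrix(4000, 900, 30, 3000, 20, 1300)
  # synthetic smooth labels standing in for FE constants
  consts <- t(vapply(designs, function(m) {
    s <- sum(m)
    c(800 * s, 120 * s, 0.5 * s, 700 * s, 0.4 * s, 90 * s)
  }, numeric(6)))
  lab <- list(constants = consts,
              f = scafmatch:::objective_rows(consts, ct, 0.34))
  sp <- cnn_spec(conv_widths = c(8, 16, 32), fc_widths = c(32, 16),
                 dropout = 0, seed = 5)
  m <- cnn_build(sp)
  m1 <- cnn_fit(m, designs, lab, ct, epochs = 60, batch_size = 16,
                val_frac = 0.2, seed = 77)
  expect_lt(m1$fit$val_mae_loss[60], m1$fit$val_mae_loss[1])
  m2 <- cnn_fit(cnn_build(sp), designs, lab, ct, epochs = 60,
                batch_size = 16, val_frac = 0.2, seed = 77)
  expect_identical(m1$fit$val_mae_loss, m2$fit$val_mae_loss)
  expect_identical(m1$fit$val_mae_objective, m2$fit$val_mae_objective)
})

test_that("training toward constant labels drives the loss to zero", {
  set.seed(31)
  designs <- lapply(1:40, function(i) encode_design(random_design()))
  ct <- elasticity_matrix(4000, 900, 30, 3000, 20, 1300)
  consts <- matrix(rep(c(5000, 800, 10, 4000, 8, 1200), each = 40), 40, 6)
  lab <- list(constants = consts,
              f = scafmatch:::objective_rows(consts, ct, 0.34))
  sp <- cnn_spec(conv_widths = c(4, 8, 8), fc_widths = c(16, 8),
                 dropout = 0, seed = 2)
  # raw capacity check: no weight averaging so convergence is direct
  m <- cnn_fit(cnn_build(sp), designs, lab, ct, epochs = 80,
               batch_size = 8, seed = 3, ema = 0)
  expect_lt(m$fit$val_mae_loss[80], 2e-3)
})

test_that("inference is deterministic and permutation-consistent", {
  set.seed(32)
  designs <- lapply(1:30, function(i) encode_design(random_design()))
  ct <- elasticity_matrix(4000, 900, 30, 3000, 20, 1300)
  consts <- t(vapply(designs, function(m) 1000 * c(sum(m), 1, 1, sum(m), 1,
                                                   sum(m)), numeric(6)))
  lab <- list(constants = consts,
              f = scafmatch:::objective_rows(consts, ct, 0.34))
  m <- cnn_fit(cnn_build(cnn_spec(conv_widths = c(4, 8, 8),
                                  fc_widths = c(8, 8), seed = 1)),
               designs, lab, ct, epochs = 3, batch_size = 8, seed = 2)
  p1 <- cnn_predict(m, designs, ct)
  p2 <- cnn_predict(m, designs, ct)
  expect_identical(p1$f, p2$f)
  perm <- sample(length(designs))
  p3 <- cnn_predict(m, designs[perm], ct)
  expect_equal(p3$f, p1$f[perm])
  # constants-head objective respects f >= 0
  expect_true(all(p1$f >= 0))
})
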