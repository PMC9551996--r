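# shared test utilities

# closed-form plane-stress stiffness of a homogeneous plate
plate_closed_form <- function(e, nu) {
  matrix(c(
    e / (1 - nu^2), nu * e / (1 - nu^2), 0,
    nu * e / (1 - nu^2), e / (1 - nu^2), 0,
    0, 0, e / (2 * (1 + nu))
  ), 3, 3, byrow = TRUE)
}

# number of 4-connected components of a logical mask (test-side oracle)
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nextlab <- nextlab + 1L
      stack <- list(c(i, j))
      lab[i, j] <- nextlab
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nextlab
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  nextlab
}

rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b))

# memoized heavy fixtures shared across acceptance tests
.accept_env <- new.env(parent = emptyenv())

accept_target <- function() {
  if (is.null(.accept_env$target)) {
    p <- synth_bone_params(size_mm = 18, pixel_pitch = 0.2, seed = 11)
    .accept_env$target <- homogenize(bone_target_model(p)$model)
  }
  .accept_env$target
}

# one scaled-down surrogate training run shared by the prediction-power and
# cross-validation acceptance tests: ~3000 FE-labelled random designs at the
# 0.2 mm raster, 80/20 split, batch 128, 200 epochs
accept_training_run <- function() {
  if (is.null(.accept_env$run)) {
    ct <- accept_target()
    designs <- random_designs(3000, seed = 21L)
    lab <- fe_label_designs(designs, ct, pixel_size = 0.2)
    model <- cnn_build(cnn_spec(seed = 1L))
    model <- cnn_fit(model, lapply(designs, encode_design), lab, ct,
                     epochs = 200, batch_size = 128, seed = 31L)
    .accept_env$run <- list(target = ct, designs = designs, labels = lab,
                            model = model)
  }
  .accept_env$run
}
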