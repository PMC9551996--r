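#' Convolutional surrogate specification
#'
#' Architecture of the small CNN that maps the 6 x 6 thickness-matrix
#' encoding of a scaffold design to its six homogenized elastic constants
#' (default head) or directly to the scalar matching objective. Three 3 x 3
#' same-padding convolution stages, each followed by max pooling and dropout
#' (rate 0.10); a 6 x 6 input cannot survive three stride-2 poolings, so the
#' third pooling is a global average. Three fully connected layers follow.
#'
#' @param conv_widths channel widths of the three convolution stages
#'   (default c(32, 64, 128)).
#' @param fc_widths sizes of the first two fully connected layers
#'   (default c(128, 64)).
#' @param head "constants" (6 outputs, objective computed downstream) or
#'   "objective" (scalar output).
#' @param dropout dropout rate at the three pooling layers (default 0.10).
#' @param seed integer seed for weight initialization.
#' @return object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_widths = c(32L, 64L, 128L),
                     fc_widths = c(128L, 64L),
                     head = c("constants", "objective"),
                     dropout = 0.10, seed = 1L) {
  head <- match.arg(head)
  stopifnot(length(conv_widths) == 3, length(fc_widths) == 2,
            dropout >= 0, dropout < 1)
  structure(list(
    conv_widths = as.integer(conv_widths),
    fc_widths = as.integer(fc_widths),
    head = head, n_out = if (head == "constants") 6L else 1L,
    dropout = dropout, seed = as.integer(seed)
  ), class = "cnn_spec")
}

# ---- low-level tensor ops -------------------------------------------------
# Activations are 3D arrays with dim (batch, spatial, channels); spatial
# positions are column-major over the (row, col) grid.

# kernel offsets of the 3 x 3 window, dy fastest; offset 10 - o is -offset o
conv_offsets <- expand.grid(dy = -1:1, dx = -1:1)

# per-offset source spatial index (NA outside) for an H x W grid
conv_gather_idx <- function(H, W) {
  s <- seq_len(H * W)
  y <- ((s - 1L) %% H) + 1L
  x <- ((s - 1L) %/% H) + 1L
  lapply(seq_len(9), function(o) {
    yy <- y + conv_offsets$dy[o]
    xx <- x + conv_offsets$dx[o]
    idx <- yy + (xx - 1L) * H
    idx[yy < 1L | yy > H | xx < 1L | xx > W] <- NA_integer_
    idx
  })
}

# row indices into rbind(M, 0) for gathering spatial positions idx
gather_rows <- function(idx, B, S) {
  r <- rep((idx - 1L) * B, each = B) + rep(seq_len(B), times = length(idx))
  r[is.na(r)] <- B * S + 1L
  r
}

conv_forward <- function(X3, W, b, idxs) {
  d <- dim(X3)
  B <- d[1]; S <- d[2]; Cin <- d[3]
  Cout <- length(b)
  M <- X3
  dim(M) <- c(B * S, Cin)
  Mpad <- rbind(M, 0)
  Y <- matrix(b, B * S, Cout, byrow = TRUE)
  for (o in 1:9) {
    R <- gather_rows(idxs[[o]], B, S)
    Y <- Y + Mpad[R, , drop = FALSE] %*% W[[o]]
  }
  dim(Y) <- c(B, S, Cout)
  list(Y = Y, Mpad = Mpad, B = B, S = S, Cin = Cin)
}

conv_backward <- function(dY3, W, cache, idxs) {
  B <- cache$B; S <- cache$S; Cin <- cache$Cin
  Cout <- dim(dY3)[3]
  dY <- dY3
  dim(dY) <- c(B * S, Cout)
  dYpad <- rbind(dY, 0)
  dW <- vector("list", 9)
  dM <- matrix(0, B * S, Cin)
  for (o in 1:9) {
    R <- gather_rows(idxs[[o]], B, S)
    dW[[o]] <- crossprod(cache$Mpad[R, , drop = FALSE], dY)
    Ri <- gather_rows(idxs[[10 - o]], B, S)
    dM <- dM + dYpad[Ri, , drop = FALSE] %*% t(W[[o]])
  }
  db <- colSums(dY)
  dim(dM) <- c(B, S, Cin)
  list(dX = dM, dW = dW, db = db)
}

# 2 x 2 stride-2 max pooling groups (ceil mode) for an H x H grid:
# list over output positions (column-major) of source spatial indices
pool_groups <- function(H) {
  ng <- ceiling(H / 2)
  bands <- lapply(seq_len(ng), function(g) (2 * g - 1):min(2 * g, H))
  out <- vector("list", ng * ng)
  k <- 1L
  for (gx in seq_len(ng)) {
    for (gy in seq_len(ng)) {
      src <- as.vector(outer(bands[[gy]], (bands[[gx]] - 1L) * H, "+"))
      out[[k]] <- src
      k <- k + 1L
    }
  }
  out
}

# slice X3[, s, ] keeping (B, C) matrix shape for any batch size
mslice <- function(X3, s) {
  m <- X3[, s, , drop = FALSE]
  dim(m) <- c(dim(X3)[1], dim(X3)[3])
  m
}

maxpool_forward <- function(X3, groups) {
  d <- dim(X3)
  B <- d[1]; C <- d[3]
  P <- length(groups)
  Y <- array(0, c(B, P, C))
  arg <- array(1L, c(B, P, C))
  for (p in seq_len(P)) {
    src <- groups[[p]]
    cur <- mslice(X3, src[1])
    ag <- matrix(1L, B, C)
    if (length(src) > 1) {
      for (k in 2:length(src)) {
        cand <- mslice(X3, src[k])
        upd <- cand > cur
        cur[upd] <- cand[upd]
        ag[upd] <- k
      }
    }
    Y[, p, ] <- cur
    arg[, p, ] <- ag
  }
  list(Y = Y, arg = arg)
}

maxpool_backward <- function(dY3, arg, groups, S_in) {
  d <- dim(dY3)
  B <- d[1]; P <- d[2]; C <- d[3]
  dX <- array(0, c(B, S_in, C))
  for (p in seq_len(P)) {
    src <- groups[[p]]
    g <- mslice(dY3, p)
    ag <- mslice(arg, p)
    for (k in seq_along(src)) {
      m <- (ag == k)
      if (any(m)) {
        dX[, src[k], ] <- mslice(dX, src[k]) + g * m
      }
    }
  }
  dX
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- model build / forward / backward ------------------------------------

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Build a convolutional surrogate
#'
#' Initializes all weights deterministically under the spec's seed
#' (He-style normal initialization scaled by fan-in).
#'
#' @param spec a [cnn_spec()].
#' @return object of class `cnn_model` (untrained).
#' @export
cnn_build <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  cw <- spec$conv_widths
  fw <- spec$fc_widths
  params <- withr_seed(spec$seed, {
    p <- list()
    cins <- c(1L, cw[1], cw[2])
    for (l in 1:3) {
      sdv <- sqrt(2 / (9 * cins[l]))
      p[[paste0("conv", l)]] <- list(
        W = lapply(1:9, function(o) init_mat(cins[l], cw[l], sdv)),
        b = numeric(cw[l])
      )
    }
    fins <- c(cw[3], fw[1], fw[2])
    fouts <- c(fw[1], fw[2], spec$n_out)
    for (l in 1:3) {
      sdv <- sqrt(2 / fins[l])
      p[[paste0("fc", l)]] <- list(
        W = init_mat(fins[l], fouts[l], sdv),
        b = numeric(fouts[l])
      )
    }
    p
  })
  structure(list(
    spec = spec, params = params,
    idx6 = conv_gather_idx(6, 6), idx3 = conv_gather_idx(3, 3),
    idx2 = conv_gather_idx(2, 2),
    grp6 = pool_groups(6), grp3 = pool_groups(3),
    norm = NULL # filled by cnn_fit: input/label normalizers
  ), class = "cnn_model")
}

# Forward pass. X: (B, 36) matrix of normalized inputs. When train = TRUE
# dropout masks are sampled from the current RNG stream and kept for the
# backward pass.
cnn_forward <- function(model, X, train = FALSE) {
  p <- model$params
  dr <- model$spec$dropout
  B <- nrow(X)
  X3 <- X
  dim(X3) <- c(B, 36L, 1L)
  cc <- list()

  c1 <- conv_forward(X3, p$conv1$W, p$conv1$b, model$idx6)
  A1 <- relu(c1$Y)
  p1 <- maxpool_forward(A1, model$grp6)
  H1 <- p1$Y
  if (train && dr > 0) {
    m1 <- array(stats::runif(length(H1)) >= dr, dim(H1)) / (1 - dr)
    H1 <- H1 * m1
    cc$m1 <- m1
  }

  c2 <- conv_forward(H1, p$conv2$W, p$conv2$b, model$idx3)
  A2 <- relu(c2$Y)
  p2 <- maxpool_forward(A2, model$grp3)
  H2 <- p2$Y
  if (train && dr > 0) {
    m2 <- array(stats::runif(length(H2)) >= dr, dim(H2)) / (1 - dr)
    H2 <- H2 * m2
    cc$m2 <- m2
  }

  c3 <- conv_forward(H2, p$conv3$W, p$conv3$b, model$idx2)
  A3 <- relu(c3$Y)
  # third pooling: global average over the 2 x 2 map
  S3 <- dim(A3)[2]
  G <- mslice(A3, 1)
  for (s in 2:S3) G <- G + mslice(A3, s)
  G <- G / S3
  if (train && dr > 0) {
    m3 <- matrix(stats::runif(length(G)) >= dr, nrow(G)) / (1 - dr)
    G <- G * m3
    cc$m3 <- m3
  }

  Z1 <- relu(sweep(G %*% p$fc1$W, 2, p$fc1$b, "+"))
  Z2 <- relu(sweep(Z1 %*% p$fc2$W, 2, p$fc2$b, "+"))
  out <- sweep(Z2 %*% p$fc3$W, 2, p$fc3$b, "+")

  list(out = out,
       cache = c(cc, list(X3 = X3, c1 = c1, A1 = A1, p1 = p1, H1 = H1,
                          c2 = c2, A2 = A2, p2 = p2, H2 = H2,
                          c3 = c3, A3 = A3, G = G, Z1 = Z1, Z2 = Z2)))
}

# Backward pass for dL/dout = dout; returns gradients in params structure.
cnn_backward <- function(model, fw, dout) {
  p <- model$params
  cc <- fw$cache
  g <- list()

  dZ2 <- dout %*% t(p$fc3$W)
  g$fc3 <- list(W = crossprod(cc$Z2, dout), b = colSums(dout))
  dZ2[cc$Z2 <= 0] <- 0
  dZ1 <- dZ2 %*% t(p$fc2$W)
  g$fc2 <- list(W = crossprod(cc$Z1, dZ2), b = colSums(dZ2))
  dZ1[cc$Z1 <= 0] <- 0
  dG <- dZ1 %*% t(p$fc1$W)
  g$fc1 <- list(W = crossprod(cc$G, dZ1), b = colSums(dZ1))

  if (!is.null(cc$m3)) dG <- dG * cc$m3
  S3 <- dim(cc$A3)[2]
  dA3 <- array(0, dim(cc$A3))
  for (s in seq_len(S3)) dA3[, s, ] <- dG / S3
  dA3[cc$A3 <= 0] <- 0
  b3 <- conv_backward(dA3, p$conv3$W, cc$c3, model$idx2)
  g$conv3 <- list(W = b3$dW, b = b3$db)

  dH2 <- b3$dX
  if (!is.null(cc$m2)) dH2 <- dH2 * cc$m2
  dA2 <- maxpool_backward(dH2, cc$p2$arg, model$grp3, dim(cc$A2)[2])
  dA2[cc$A2 <= 0] <- 0
  b2 <- conv_backward(dA2, p$conv2$W, cc$c2, model$idx3)
  g$conv2 <- list(W = b2$dW, b = b2$db)

  dH1 <- b2$dX
  if (!is.null(cc$m1)) dH1 <- dH1 * cc$m1
  dA1 <- maxpool_backward(dH1, cc$p1$arg, model$grp6, dim(cc$A1)[2])
  dA1[cc$A1 <= 0] <- 0
  b1 <- conv_backward(dA1, p$conv1$W, cc$c1, model$idx6)
  g$conv1 <- list(W = b1$dW, b = b1$db)

  g
}

# Adam update walking the nested params/grad structure.
adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (ln in names(state$params)) {
    lay <- state$params[[ln]]
    if (is.list(lay$W)) {
      for (o in seq_along(lay$W)) {
        r <- upd(lay$W[[o]], grads[[ln]]$W[[o]],
                 state$m[[ln]]$W[[o]], state$v[[ln]]$W[[o]])
        state$params[[ln]]$W[[o]] <- r$p
        state$m[[ln]]$W[[o]] <- r$m
        state$v[[ln]]$W[[o]] <- r$v
      }
    } else {
      r <- upd(lay$W, grads[[ln]]$W, state$m[[ln]]$W, state$v[[ln]]$W)
      state$params[[ln]]$W <- r$p
      state$m[[ln]]$W <- r$m
      state$v[[ln]]$W <- r$v
    }
    rb <- upd(lay$b, grads[[ln]]$b, state$m[[ln]]$b, state$v[[ln]]$b)
    state$params[[ln]]$b <- rb$p
    state$m[[ln]]$b <- rb$m
    state$v[[ln]]$b <- rb$v
  }
  state
}

zeros_like_params <- function(params) {
  rapply(params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }, how = "replace")
}

# exponential moving average of two parameter structures: d*a + (1-d)*b
ema_params <- function(a, b, d) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- ema_params(a[[nm]], b[[nm]], d)
    out
  } else {
    d * a + (1 - d) * b
  }
}

# ---- user-facing training / prediction -----------------------------------

# designs: list of 6 x 6 thickness matrices -> (n, 36) normalized input
designs_to_input <- function(designs, levels = c(0.2, 0.6)) {
  X <- t(vapply(designs, function(m) as.vector(m), numeric(36)))
  (X - levels[1]) / (levels[2] - levels[1])
}

# weights for the vectorized objective over the six constants
# (c11, c12, c13, c22, c23, c33); symmetric off-diagonal counted twice
constant_weights <- function(nu) {
  wm <- weight_matrix(nu)
  c(wm$w[1, 1], 2 * wm$w[1, 2], 0, wm$w[2, 2], 0, wm$w[3, 3]) / wm$w_hat
}

# vectorized objective for an (n, 6) matrix of constants vs a target
objective_rows <- function(Cmat, c_target, nu) {
  ct <- c(c_target$c11, c_target$c12, c_target$c13,
          c_target$c22, c_target$c23, c_target$c33)
  wv <- constant_weights(nu)
  A <- sweep(sweep(Cmat, 2, ct, "-"), 2, ct, "/")^2
  A[, wv == 0] <- 0
  as.vector(A %*% wv)
}

#' Finite-element labels for a set of scaffold designs
#'
#' Homogenizes each design at the given raster pitch (reusing one sparse
#' solver) and evaluates the matching objective against the target.
#'
#' @param designs list of [scaffold_design()]s.
#' @param c_target target [elasticity_matrix()].
#' @param nu_material base-material Poisson's ratio (default 0.34).
#' @param pixel_size raster pitch in mm (default 0.2).
#' @param e_solid solid modulus in MPa (default 113800).
#' @param progress print progress every so many designs (0 = quiet).
#' @param solver optional reusable [grid_solver()] matching the raster.
#' @return list with `constants` (n x 6 matrix), `f` (length-n vector) and
#'   `matrices` (list of [elasticity_matrix()]).
#' @export
fe_label_designs <- function(designs, c_target, nu_material = 0.34,
                             pixel_size = 0.2, e_solid = 113800,
                             progress = 0, solver = NULL) {
  n <- length(designs)
  gs <- solver
  if (is.null(gs)) {
    npx <- as.integer(round(designs[[1]]$cell_size * 3 / pixel_size))
    gs <- grid_solver(npx, npx, nu_material, pixel_size)
  }
  constants <- matrix(0, n, 6)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    cm <- homogenize_design(designs[[i]], pixel_size = pixel_size,
                            e_solid = e_solid, poisson = nu_material,
                            solver = gs)
    constants[i, ] <- c(cm$c11, cm$c12, cm$c13, cm$c22, cm$c23, cm$c33)
    mats[[i]] <- cm
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("FE-labelled %d / %d designs", i, n))
    }
  }
  f <- objective_rows(constants, c_target, nu_material)
  list(constants = constants, f = f, matrices = mats)
}

#' Train the convolutional surrogate on finite-element labels
#'
#' Trains with mini-batch Adam on a mean-absolute-error loss. Inputs are the
#' 6 x 6 thickness matrices normalized to {0, 0.5, 1}; constant labels are
#' normalized by the solid-plate c11 reference. The held-out split is scored
#' every epoch with two curves: the loss-scale MAE on normalized labels and
#' the objective-scale MAE (mean |f_FE - f_CNN|) used for cross-validation.
#'
#' @param model a [cnn_build()] model.
#' @param designs list of 6 x 6 design matrices (from [encode_design()]).
#' @param labels output of [fe_label_designs()] for the same designs.
#' @param c_target target [elasticity_matrix()] (for the objective-scale
#'   validation curve and the "objective" head labels).
#' @param nu_material base-material Poisson's ratio (default 0.34).
#' @param epochs training epochs (default 200).
#' @param batch_size mini-batch size (default 128).
#' @param val_frac held-out fraction (default 0.2, i.e. an 80/20 split).
#' @param lr initial Adam learning rate (default 1e-3).
#' @param lr_decay,lr_decay_every optional step decay schedule: the learning
#'   rate is multiplied by `lr_decay` every `lr_decay_every` epochs. The
#'   default `lr_decay = 1` keeps the rate constant: the fit is
#'   optimization-limited at these problem sizes, so decaying the rate
#'   freezes progress early; late-training noise is handled by the Polyak
#'   average instead.
#' @param ema decay of the Polyak (exponential moving) average of the
#'   weights; the averaged weights are what the per-epoch validation curve
#'   scores and what the returned model carries. 0 disables averaging
#'   (default 0.995, bias-corrected; with ~19 batches per epoch this
#'   averages over roughly the last 10 epochs and removes most
#'   mini-batch/dropout noise from the validation curve).
#' @param seed seed for the split, shuffling, and dropout.
#' @param e_solid solid modulus defining the label normalizer.
#' @param verbose print the validation MAE every so many epochs (0 = quiet).
#' @return the trained `cnn_model` with a `fit` component carrying the
#'   normalizers, split indices and per-epoch validation curves.
#' @export
cnn_fit <- function(model, designs, labels, c_target, nu_material = 0.34,
                    epochs = 200L, batch_size = 128L, val_frac = 0.2,
                    lr = 1e-3, lr_decay = 1, lr_decay_every = 80L,
                    ema = 0.995, seed = 1L, e_solid = 113800, verbose = 0) {
  stopifnot(inherits(model, "cnn_model"))
  n <- length(designs)
  X <- designs_to_input(designs)
  c_ref <- e_solid / (1 - nu_material^2) # solid-plate c11
  if (model$spec$head == "constants") {
    Y <- labels$constants / c_ref
  } else {
    Y <- matrix(labels$f, ncol = 1)
  }

  state <- list(params = model$params,
                m = zeros_like_params(model$params),
                v = zeros_like_params(model$params), t = 0L)
  # bias-corrected Polyak average: avg accumulates from zero and is divided
  # by (1 - ema^t) when read, so early epochs are not dragged toward the
  # random initialization
  avg <- zeros_like_params(model$params)
  n_avg <- 0L

  curves <- withr_seed(seed, {
    idx <- sample.int(n)
    nval <- max(1L, round(val_frac * n))
    val <- idx[seq_len(nval)]
    tr <- idx[-seq_len(nval)]
    Xtr <- X[tr, , drop = FALSE]
    Ytr <- Y[tr, , drop = FALSE]
    Xval <- X[val, , drop = FALSE]
    fval <- labels$f[val]
    Yval <- Y[val, , drop = FALSE]

    val_mae_loss <- numeric(epochs)
    val_mae_objective <- numeric(epochs)
    ntr <- length(tr)
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * lr_decay^((ep - 1L) %/% lr_decay_every)
      ord <- sample.int(ntr)
      for (b0 in seq(1, ntr, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, ntr)]
        model$params <- state$params
        fw <- cnn_forward(model, Xtr[bi, , drop = FALSE], train = TRUE)
        resid <- fw$out - Ytr[bi, , drop = FALSE]
        dout <- sign(resid) / length(resid)
        grads <- cnn_backward(model, fw, dout)
        state <- adam_step(state, grads, lr_ep)
        if (ema > 0) {
          avg <- ema_params(avg, state$params, ema)
          n_avg <- n_avg + 1L
        }
      }
      model$params <- if (ema > 0) {
        corr <- 1 / (1 - ema^n_avg)
        rapply(avg, function(x) x * corr, how = "replace")
      } else {
        state$params
      }
      pv <- cnn_forward(model, Xval, train = FALSE)$out
      val_mae_loss[ep] <- mean(abs(pv - Yval))
      if (model$spec$head == "constants") {
        fcnn <- objective_rows(pv * c_ref, c_target, nu_material)
      } else {
        fcnn <- as.vector(pv)
      }
      val_mae_objective[ep] <- mae(fval, fcnn)
      if (verbose > 0 && ep %% verbose == 0) {
        message(sprintf("epoch %3d: val MAE (loss scale) %.5f, (objective) %.4f",
                        ep, val_mae_loss[ep], val_mae_objective[ep]))
      }
    }
    list(val_mae_loss = val_mae_loss,
         val_mae_objective = val_mae_objective,
         train_idx = tr, val_idx = val)
  })

  model$params <- if (ema > 0) model$params else state$params
  model$fit <- list(
    c_ref = c_ref, nu_material = nu_material, e_solid = e_solid,
    epochs = epochs, batch_size = batch_size, lr = lr, seed = seed,
    val_mae_loss = curves$val_mae_loss,
    val_mae_objective = curves$val_mae_objective,
    train_idx = curves$train_idx, val_idx = curves$val_idx
  )
  model
}

#' Surrogate predictions for scaffold designs
#'
#' @param model a trained `cnn_model` (dropout disabled at inference).
#' @param designs list of 6 x 6 design matrices.
#' @param c_target target [elasticity_matrix()]; required for the constants
#'   head to evaluate the downstream objective.
#' @param nu_material base-material Poisson's ratio.
#' @return list with `f` (predicted objective values) and, for the constants
#'   head, `constants` (n x 6 matrix, MPa).
#' @export
cnn_predict <- function(model, designs, c_target = NULL,
                        nu_material = 0.34) {
  stopifnot(inherits(model, "cnn_model"))
  X <- designs_to_input(designs)
  n <- nrow(X)
  out <- matrix(0, n, model$spec$n_out)
  for (b0 in seq(1, n, by = 512L)) {
    bi <- b0:min(b0 + 511L, n)
    out[bi, ] <- cnn_forward(model, X[bi, , drop = FALSE], train = FALSE)$out
  }
  if (model$spec$head == "constants") {
    if (is.null(model$fit)) stop("model must be trained before prediction")
    Cmat <- out * model$fit$c_ref
    if (is.null(c_target)) {
      return(list(constants = Cmat, f = NULL))
    }
    list(constants = Cmat,
         f = objective_rows(Cmat, c_target, nu_material))
  } else {
    list(f = as.vector(out))
  }
}

#' Prediction-power evaluation of a trained surrogate
#'
#' Draws `n_eval` fresh random designs, computes their objectives by both
#' the finite element method and the surrogate, log-transforms both series
#' with a common reference maximum, and reports the coefficient of
#' determination together with a Bland-Altman agreement analysis of the
#' untransformed objectives.
#'
#' @param model trained `cnn_model`.
#' @param c_target target [elasticity_matrix()].
#' @param n_eval number of evaluation designs (default 500).
#' @param nu_material,pixel_size,e_solid finite element settings.
#' @param seed seed for the evaluation designs.
#' @return list with `f_fe`, `f_cnn`, `log_fe`, `log_cnn`, `r_squared`,
#'   and `bland_altman` (see [bland_altman()]).
#' @export
evaluate_power <- function(model, c_target, n_eval = 500L,
                           nu_material = 0.34, pixel_size = 0.2,
                           e_solid = 113800, seed = 99L) {
  if (n_eval < 2) stop("n_eval must be >= 2")
  designs <- withr_seed(seed, {
    lapply(seq_len(n_eval), function(i) random_design())
  })
  lab <- fe_label_designs(designs, c_target, nu_material = nu_material,
                          pixel_size = pixel_size, e_solid = e_solid)
  mats <- lapply(designs, encode_design)
  pred <- cnn_predict(model, mats, c_target, nu_material)
  f_fe <- lab$f
  f_cnn <- pmax(pred$f, 1e-12) # the log transform needs positive values
  f_max <- max(c(f_fe, f_cnn))
  lfe <- log_transform(f_fe, f_max)
  lcnn <- log_transform(f_cnn, f_max)
  list(
    f_fe = f_fe, f_cnn = f_cnn, log_fe = lfe, log_cnn = lcnn,
    r_squared = r_squared(lfe, lcnn),
    bland_altman = bland_altman(f_fe, f_cnn)
  )
}
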