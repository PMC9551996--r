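#' Weighting matrix for the stiffness-matching objective
#'
#' Entry weights chosen so each elastic constant plays an approximately equal
#' role in the objective: w11 = w22 = 1/(1 - nu^2), w12 = w21 = nu/(1 - nu^2),
#' w33 = 1/(2 (1 + nu)), and zero for the (1,3)/(2,3) entries, whose
#' contribution to the in-plane anisotropy of the wall lattice is negligible.
#' `nu` is the Poisson's ratio of the scaffold base material.
#'
#' @param nu Poisson's ratio in (0, 0.5) (default 0.34, Ti-6Al-4V).
#' @return list with the 3 x 3 weight matrix `w` and its total `w_hat`.
#' @export
weight_matrix <- function(nu = 0.34) {
  if (!(nu > 0 && nu < 0.5)) stop("nu must be in (0, 0.5)")
  w <- matrix(0, 3, 3)
  w[1, 1] <- w[2, 2] <- 1 / (1 - nu^2)
  w[1, 2] <- w[2, 1] <- nu / (1 - nu^2)
  w[3, 3] <- 1 / (2 * (1 + nu))
  list(w = w, w_hat = sum(w))
}

#' Relative squared differences between two elasticity matrices
#'
#' a_ij = ((c'_ij - c_ij) / c_ij)^2 for entries with nonzero weight; the
#' squaring magnifies differences and removes signs. Zero-weight entries
#' ((1,3) and (2,3)) are set to 0 without ever dividing, so a near-zero
#' target c13 never faults.
#'
#' @param c_scaffold,c_target [elasticity_matrix()] objects (scaffold and
#'   target/bone).
#' @param nu Poisson's ratio defining which weights are nonzero.
#' @param tol relative division-guard tolerance (default 1e-9).
#' @return 3 x 3 matrix of relative squared differences.
#' @export
relative_sq_diff <- function(c_scaffold, c_target, nu = 0.34, tol = 1e-9) {
  cs <- as.matrix(c_scaffold)
  ct <- as.matrix(c_target)
  w <- weight_matrix(nu)$w
  a <- matrix(0, 3, 3)
  cmax <- max(abs(ct))
  for (i in 1:3) for (j in 1:3) {
    if (w[i, j] == 0) next
    if (abs(ct[i, j]) <= tol * cmax) {
      stop(sprintf("target entry c%d%d is within the division guard", i, j))
    }
    a[i, j] <- ((cs[i, j] - ct[i, j]) / ct[i, j])^2
  }
  a
}

#' Stiffness-matching objective
#'
#' f = sum over all nine (i, j) of (w_ij / w_hat) a_ij; symmetric
#' off-diagonal entries are counted twice, consistent with w_hat summing both
#' w12 and w21. f >= 0 with equality iff every weighted constant matches.
#'
#' @inheritParams relative_sq_diff
#' @return list of class `objective_result` with the per-entry grid `a`,
#'   the scalar objective `f`, and the weights used.
#' @export
objective <- function(c_scaffold, c_target, nu = 0.34, tol = 1e-9) {
  wm <- weight_matrix(nu)
  a <- relative_sq_diff(c_scaffold, c_target, nu = nu, tol = tol)
  f <- sum(wm$w / wm$w_hat * a)
  structure(list(a = a, f = f, w = wm$w, w_hat = wm$w_hat),
            class = "objective_result")
}

# Objective from the six constants as a plain numeric vector
# (c11, c12, c13, c22, c23, c33); used on surrogate predictions.
objective_from_constants <- function(cvec, c_target, nu = 0.34) {
  cm <- elasticity_matrix(cvec[1], cvec[2], cvec[3], cvec[4], cvec[5], cvec[6])
  objective(cm, c_target, nu = nu)$f
}

#' Logarithmic transform of objective values
#'
#' Log_f = (ln f + 1) / ln f_max, with f_max the maximal objective in the
#' dataset being transformed. Compresses the variance growth of the
#' objective with its amplitude before correlation analysis.
#'
#' @param f positive objective value(s).
#' @param f_max reference maximum, must exceed 1.
#' @return transformed value(s).
#' @export
log_transform <- function(f, f_max) {
  if (any(f <= 0)) stop("log_transform requires f > 0; report untransformed")
  if (!(f_max > 1)) stop("f_max must be > 1")
  (log(f) + 1) / log(f_max)
}

#' Mean absolute error
#'
#' @param truth,pred equal-length numeric vectors.
#' @return mean of |truth - pred|.
#' @export
mae <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (length(truth) < 1) stop("need at least one pair")
  mean(abs(truth - pred))
}

#' Signed relative error
#'
#' (p_designed - p_target) / p_target; multiply by 100 for percent.
#'
#' @param p_designed,p_target scalars or vectors; `p_target` must be nonzero.
#' @return signed relative error as a fraction.
#' @export
relative_error <- function(p_designed, p_target) {
  if (any(p_target == 0)) stop("p_target must be nonzero")
  (p_designed - p_target) / p_target
}
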