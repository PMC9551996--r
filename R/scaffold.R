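#' Discrete wall-lattice scaffold design
#'
#' A 3 x 3 grid of square cells (cell edge 6 mm, overall 18 x 18 mm). Each
#' cell carries four wall thicknesses -- left, top, bottom, right -- drawn
#' inward from its own four edges, giving 36 independent design variables,
#' each restricted to the discrete set {0.2, 0.4, 0.6} mm (the lower bound is
#' the minimal strut thickness printable by selective laser melting).
#'
#' Thicknesses are stored as a 3 x 3 x 4 array indexed by
#' (cell_row, cell_col, wall) with walls ordered left, top, bottom, right.
#' Cell row 1 is the low-y band of the raster (no image flip); "top" denotes
#' the low-row edge of the cell block and "bottom" the high-row edge.
#'
#' @param thickness numeric vector of 36 values (cell-major, walls fastest in
#'   the order left, top, bottom, right; cells in row-major order), or a
#'   3 x 3 x 4 array.
#' @param cell_size cell edge length in mm (default 6).
#' @param levels allowed thickness values in mm (default c(0.2, 0.4, 0.6)).
#' @return object of class `scaffold_design`.
#' @export
scaffold_design <- function(thickness, cell_size = 6,
                            levels = c(0.2, 0.4, 0.6)) {
  if (is.array(thickness) && length(dim(thickness)) == 3) {
    stopifnot(all(dim(thickness) == c(3, 3, 4)))
    arr <- thickness
  } else {
    thickness <- as.numeric(thickness)
    if (length(thickness) != 36) stop("need 36 thickness values")
    # vector order: cell (1,1) walls LTBR, cell (1,2) walls LTBR, ...
    arr <- array(0, c(3, 3, 4))
    k <- 1L
    for (r in 1:3) for (cc in 1:3) for (w in 1:4) {
      arr[r, cc, w] <- thickness[k]
      k <- k + 1L
    }
  }
  ok <- vapply(as.vector(arr),
               function(t) any(abs(t - levels) < 1e-9), logical(1))
  if (!all(ok)) {
    stop("every thickness must be one of {",
         paste(levels, collapse = ", "), "} mm (no snapping)")
  }
  if (2 * max(levels) >= cell_size) stop("2 * max thickness must be < cell_size")
  structure(list(thickness = arr, cell_size = cell_size, levels = levels),
            class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf("scaffold_design: 3 x 3 cells of %.3g mm, 36 walls\n",
              x$cell_size))
  print(encode_design(x))
  invisible(x)
}

design_vector <- function(design) {
  out <- numeric(36)
  k <- 1L
  for (r in 1:3) for (cc in 1:3) for (w in 1:4) {
    out[k] <- design$thickness[r, cc, w]
    k <- k + 1L
  }
  out
}

#' Encode a scaffold design as a 6 x 6 matrix
#'
#' Cell (r, c) maps to the 2 x 2 block with rows {2r-1, 2r} and columns
#' {2c-1, 2c}; within the block the order is (1,1) = left, (1,2) = top,
#' (2,1) = bottom, (2,2) = right. The encoding is a bijection:
#' `decode_design(encode_design(d))` returns `d`.
#'
#' @param design a [scaffold_design()].
#' @return a 6 x 6 numeric matrix of thicknesses (mm).
#' @export
encode_design <- function(design) {
  stopifnot(inherits(design, "scaffold_design"))
  m <- matrix(0, 6, 6)
  for (r in 1:3) for (cc in 1:3) {
    t4 <- design$thickness[r, cc, ]
    m[2 * r - 1, 2 * cc - 1] <- t4[1] # left
    m[2 * r - 1, 2 * cc] <- t4[2] # top
    m[2 * r, 2 * cc - 1] <- t4[3] # bottom
    m[2 * r, 2 * cc] <- t4[4] # right
  }
  m
}

#' Decode a 6 x 6 design matrix back to a scaffold design
#'
#' Exact inverse of [encode_design()].
#'
#' @param m a 6 x 6 numeric matrix with entries on the thickness lattice.
#' @param cell_size,levels see [scaffold_design()].
#' @return a [scaffold_design()].
#' @export
decode_design <- function(m, cell_size = 6, levels = c(0.2, 0.4, 0.6)) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(6, 6)))
  arr <- array(0, c(3, 3, 4))
  for (r in 1:3) for (cc in 1:3) {
    arr[r, cc, 1] <- m[2 * r - 1, 2 * cc - 1]
    arr[r, cc, 2] <- m[2 * r - 1, 2 * cc]
    arr[r, cc, 3] <- m[2 * r, 2 * cc - 1]
    arr[r, cc, 4] <- m[2 * r, 2 * cc]
  }
  scaffold_design(arr, cell_size = cell_size, levels = levels)
}

#' Rasterize a scaffold design to a binary solid mask
#'
#' Each cell contributes four rectangular walls drawn inward from its own
#' four edges, each spanning the full edge; the solid region is the union of
#' all walls across cells, so abutting walls of neighboring cells stack
#' (combined width t_a + t_b across a shared cell boundary).
#'
#' @param design a [scaffold_design()].
#' @param pixel_size raster pitch in mm; cell size and all thicknesses must
#'   be integer multiples (default 0.1 mm, i.e. 2/4/6 px walls).
#' @return logical matrix (TRUE = solid), 180 x 180 at the default pitch.
#' @export
rasterize_mask <- function(design, pixel_size = 0.1) {
  stopifnot(inherits(design, "scaffold_design"))
  cs <- design$cell_size
  cpx <- cs / pixel_size
  if (abs(cpx - round(cpx)) > 1e-9) {
    stop("cell_size must be an integer multiple of pixel_size")
  }
  cpx <- as.integer(round(cpx))
  tpx <- design$thickness / pixel_size
  if (any(abs(tpx - round(tpx)) > 1e-9)) {
    stop("all thicknesses must be integer multiples of pixel_size")
  }
  tpx <- round(tpx)
  n <- 3L * cpx
  mask <- matrix(FALSE, n, n)
  for (r in 1:3) for (cc in 1:3) {
    r0 <- (r - 1L) * cpx # rows r0+1 .. r0+cpx
    c0 <- (cc - 1L) * cpx
    rows <- (r0 + 1L):(r0 + cpx)
    cols <- (c0 + 1L):(c0 + cpx)
    tl <- tpx[r, cc, 1]; tt <- tpx[r, cc, 2]
    tb <- tpx[r, cc, 3]; tr <- tpx[r, cc, 4]
    if (tl > 0) mask[rows, (c0 + 1L):(c0 + tl)] <- TRUE
    if (tr > 0) mask[rows, (c0 + cpx - tr + 1L):(c0 + cpx)] <- TRUE
    if (tt > 0) mask[(r0 + 1L):(r0 + tt), cols] <- TRUE
    if (tb > 0) mask[(r0 + cpx - tb + 1L):(r0 + cpx), cols] <- TRUE
  }
  mask
}

#' Rasterize a scaffold design to a voxel plane-stress model
#'
#' Solid pixels receive the base-material modulus (Ti-6Al-4V by default,
#' E = 113.8 GPa), void pixels the floor stiffness `e_floor`.
#'
#' @inheritParams rasterize_mask
#' @param e_solid solid modulus in MPa (default 113800).
#' @param poisson Poisson's ratio of the base material (default 0.34).
#' @param e_floor void stiffness in MPa (default 1e-6 * e_solid).
#' @return a [plane_stress_model()].
#' @export
rasterize_design <- function(design, pixel_size = 0.1, e_solid = 113800,
                             poisson = 0.34, e_floor = 1e-6 * e_solid) {
  mask <- rasterize_mask(design, pixel_size)
  e <- matrix(e_floor, nrow(mask), ncol(mask))
  e[mask] <- e_solid
  plane_stress_model(e, poisson, pixel_size)
}

#' Porosity of a scaffold design
#'
#' One minus the solid area fraction of the rasterized design.
#'
#' @inheritParams rasterize_mask
#' @return porosity fraction in (0, 1).
#' @export
porosity <- function(design, pixel_size = 0.1) {
  mask <- rasterize_mask(design, pixel_size)
  1 - mean(mask)
}

#' Draw a random scaffold design
#'
#' 36 i.i.d. uniform draws from the discrete thickness set, deterministic
#' under `seed`.
#'
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param cell_size,levels see [scaffold_design()].
#' @return a [scaffold_design()].
#' @export
random_design <- function(seed = NULL, cell_size = 6,
                          levels = c(0.2, 0.4, 0.6)) {
  draw <- function() {
    scaffold_design(sample(levels, 36, replace = TRUE),
                    cell_size = cell_size, levels = levels)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Draw a batch of distinct random scaffold designs
#'
#' Uniform draws from the discrete lattice with duplicates rejected, so the
#' returned designs are pairwise distinct; deterministic under `seed`.
#'
#' @param n number of designs.
#' @param seed integer seed.
#' @param cell_size,levels see [scaffold_design()].
#' @return list of `n` distinct [scaffold_design()]s.
#' @export
random_designs <- function(n, seed = 1L, cell_size = 6,
                           levels = c(0.2, 0.4, 0.6)) {
  withr_seed(seed, {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", n)
    i <- 0L
    while (i < n) {
      d <- random_design(cell_size = cell_size, levels = levels)
      k <- design_key(d)
      if (!is.null(seen[[k]])) next
      assign(k, TRUE, envir = seen)
      i <- i + 1L
      out[[i]] <- d
    }
    out
  })
}

#' Enumerate all periodic scaffold designs
#'
#' All 3^4 = 81 designs in which every cell repeats the same
#' (left, top, bottom, right) thickness tuple -- the conventional design
#' space with a periodic cell and four independent variables.
#'
#' @param cell_size,levels see [scaffold_design()].
#' @return list of 81 [scaffold_design()]s.
#' @export
enumerate_periodic <- function(cell_size = 6, levels = c(0.2, 0.4, 0.6)) {
  grid <- expand.grid(l = levels, t = levels, b = levels, r = levels,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    t4 <- as.numeric(grid[i, ])
    arr <- array(0, c(3, 3, 4))
    for (w in 1:4) arr[, , w] <- t4[w]
    scaffold_design(arr, cell_size = cell_size, levels = levels)
  })
}

#' Homogenize a scaffold design
#'
#' Convenience wrapper: rasterize then run the three-load-case homogenizer.
#'
#' @inheritParams rasterize_design
#' @param magnitude applied strain magnitude (default 0.1).
#' @param solver optional reusable [grid_solver()] matching the raster shape.
#' @return an [elasticity_matrix()].
#' @export
homogenize_design <- function(design, pixel_size = 0.1, e_solid = 113800,
                              poisson = 0.34, e_floor = 1e-6 * e_solid,
                              magnitude = 0.1, solver = NULL) {
  model <- rasterize_design(design, pixel_size, e_solid, poisson, e_floor)
  homogenize(model, magnitude = magnitude, solver = solver)
}
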