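#' Plane-stress voxel model
#'
#' A regular grid of 4-node bilinear plane-stress elements, one element per
#' pixel, each with its own Young's modulus and a single Poisson's ratio.
#' Row `i`, column `j` of the modulus matrix is the element with centroid at
#' `x = (j - 1/2) * element_size`, `y = (i - 1/2) * element_size` (row 1 sits
#' at `y = 0`; no image flip).
#'
#' @param modulus numeric matrix of per-element Young's moduli in MPa;
#'   all entries must be strictly positive (void regions carry a small
#'   floor stiffness rather than zero).
#' @param poisson Poisson's ratio, in (0, 0.5).
#' @param element_size element edge length in mm.
#' @return an object of class `plane_stress_model`.
#' @export
plane_stress_model <- function(modulus, poisson, element_size) {
  modulus <- as.matrix(modulus)
  stopifnot(is.numeric(modulus), all(is.finite(modulus)))
  if (any(modulus <= 0)) {
    stop("all element moduli must be > 0; give void elements a floor stiffness")
  }
  if (!(poisson > 0 && poisson < 0.5)) stop("poisson must be in (0, 0.5)")
  if (!(element_size > 0)) stop("element_size must be > 0")
  structure(
    list(modulus = modulus, poisson = poisson, element_size = element_size),
    class = "plane_stress_model"
  )
}

#' @export
print.plane_stress_model <- function(x, ...) {
  cat(sprintf(
    "plane_stress_model: %d x %d elements, %.3g mm/element, nu = %.3g\n",
    nrow(x$modulus), ncol(x$modulus), x$element_size, x$poisson
  ))
  cat(sprintf(
    "  E range: [%.4g, %.4g] MPa\n",
    min(x$modulus), max(x$modulus)
  ))
  invisible(x)
}

#' Macroscopic load case
#'
#' One canonical applied macroscopic strain state: exactly one of `eps_x`,
#' `eps_y`, `gamma_xy` is nonzero. `gamma_xy` is an engineering shear strain.
#'
#' @param eps_x,eps_y,gamma_xy applied macroscopic strain components.
#' @return an object of class `load_case`.
#' @export
load_case <- function(eps_x = 0, eps_y = 0, gamma_xy = 0) {
  nz <- c(eps_x, eps_y, gamma_xy) != 0
  if (sum(nz) != 1) {
    stop("a canonical load case has exactly one nonzero strain component")
  }
  structure(
    list(eps_x = eps_x, eps_y = eps_y, gamma_xy = gamma_xy),
    class = "load_case"
  )
}

# Bilinear quadrilateral element stiffness for a square element of unit
# Young's modulus (plane stress, unit thickness, 2x2 Gauss quadrature).
# For a square element the result is independent of the edge length.
# Node order: (0,0), (1,0), (1,1), (0,1) in local coordinates, CCW.
element_stiffness_unit <- function(poisson, edge = 1) {
  nu <- poisson
  D <- matrix(c(
    1, nu, 0,
    nu, 1, 0,
    0, 0, (1 - nu) / 2
  ), 3, 3, byrow = TRUE) / (1 - nu^2)
  gp <- c(-1, 1) / sqrt(3)
  ke <- matrix(0, 8, 8)
  for (xi in gp) {
    for (eta in gp) {
      B <- bmat_square(xi, eta, edge)
      ke <- ke + t(B) %*% D %*% B * (edge^2 / 4)
    }
  }
  ke
}

# Strain-displacement matrix of the square bilinear quad at local (xi, eta).
bmat_square <- function(xi, eta, edge) {
  # dN/dxi, dN/deta for N1..N4 at (xi, eta); local coords in [-1, 1]^2
  dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
  dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
  # physical derivatives: jacobian of the square element is (edge/2) I
  dNdx <- dNdxi * 2 / edge
  dNdy <- dNdeta * 2 / edge
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNdx
  B[2, seq(2, 8, 2)] <- dNdy
  B[3, seq(1, 8, 2)] <- dNdy
  B[3, seq(2, 8, 2)] <- dNdx
  B
}

# A reusable sparse solver for a fixed grid geometry and Poisson ratio.
# Precomputes the assembly maps and the symbolic Cholesky factorization so
# that repeated homogenization over grids of the same shape (e.g. thousands
# of scaffold designs) only pays for numeric refactorization.
#
# nx, ny: elements along x (columns) and y (rows).
grid_solver <- function(nx, ny, poisson, element_size) {
  nnx <- nx + 1L
  nny <- ny + 1L
  nnode <- nnx * nny
  ndof <- 2L * nnode
  nel <- nx * ny

  ke <- element_stiffness_unit(poisson)
  kevec <- as.vector(ke) # column-major, 64 entries

  # element -> global node ids; element e = (ex, ey) with ex fastest
  ex <- rep(0:(nx - 1L), times = ny)
  ey <- rep(0:(ny - 1L), each = nx)
  n1 <- ey * nnx + ex + 1L # lower-left
  n2 <- n1 + 1L # lower-right
  n3 <- n2 + nnx # upper-right
  n4 <- n1 + nnx # upper-left
  nodes <- cbind(n1, n2, n3, n4)
  dofmat <- matrix(0L, nel, 8L)
  dofmat[, c(1L, 3L, 5L, 7L)] <- 2L * nodes - 1L
  dofmat[, c(2L, 4L, 6L, 8L)] <- 2L * nodes

  # boundary nodes carry the affine Dirichlet data
  ix <- rep(0:(nx), times = nny)
  iy <- rep(0:(ny), each = nnx)
  boundary_node <- ix == 0L | ix == nx | iy == 0L | iy == ny
  constrained <- rep(boundary_node, each = 2L)
  free <- !constrained
  nf <- sum(free)
  # global dof -> free / constrained running index
  fidx <- integer(ndof)
  fidx[free] <- seq_len(nf)
  cidx <- integer(ndof)
  cidx[constrained] <- seq_len(sum(constrained))

  # all 64 (row, col) pairs per element, element-major
  rows <- dofmat[, rep(1:8, times = 8)] # i index of ke entry (column-major)
  cols <- dofmat[, rep(1:8, each = 8)]
  rows <- as.integer(t(rows)) # per element: 64 consecutive entries
  cols <- as.integer(t(cols))
  eidx <- rep(seq_len(nel), each = 64L)
  kidx <- rep(1:64, times = nel)

  rfree <- free[rows]
  cfree <- free[cols]

  # free-free block: keep upper triangle (fi <= fj) for symmetric storage
  selff <- rfree & cfree
  fi <- fidx[rows[selff]]
  fj <- fidx[cols[selff]]
  upper <- fi <= fj
  fi <- fi[upper]
  fj <- fj[upper]
  ff_e <- eidx[selff][upper]
  ff_k <- kidx[selff][upper]
  keyff <- (as.numeric(fj) - 1) * nf + as.numeric(fi) # column-major order
  off <- order(keyff)
  fi <- fi[off]; fj <- fj[off]; ff_e <- ff_e[off]; ff_k <- ff_k[off]
  keyff <- keyff[off]
  newcol <- c(TRUE, keyff[-1] != keyff[-length(keyff)])
  posff <- cumsum(newcol) # slot in @x for each triplet
  nnzff <- posff[length(posff)]
  ui <- fi[newcol]
  uj <- fj[newcol]
  pp <- c(0L, cumsum(tabulate(uj, nbins = nf)))
  Kff <- methods::new("dsCMatrix",
    uplo = "U", i = ui - 1L, p = as.integer(pp),
    x = numeric(nnzff), Dim = c(nf, nf)
  )

  # free-constrained block (for the Dirichlet right-hand side)
  selfc <- rfree & !cfree
  gi <- fidx[rows[selfc]]
  gj <- cidx[cols[selfc]]
  fc_e <- eidx[selfc]
  fc_k <- kidx[selfc]
  nc <- sum(constrained)
  keyfc <- (as.numeric(gj) - 1) * nf + as.numeric(gi)
  ofc <- order(keyfc)
  gi <- gi[ofc]; gj <- gj[ofc]; fc_e <- fc_e[ofc]; fc_k <- fc_k[ofc]
  keyfc <- keyfc[ofc]
  newcolc <- c(TRUE, keyfc[-1] != keyfc[-length(keyfc)])
  posfc <- cumsum(newcolc)
  nnzfc <- posfc[length(posfc)]
  ci <- gi[newcolc]
  cj <- gj[newcolc]
  ppc <- c(0L, cumsum(tabulate(cj, nbins = nc)))
  Kfc <- methods::new("dgCMatrix",
    i = ci - 1L, p = as.integer(ppc),
    x = numeric(nnzfc), Dim = c(nf, as.integer(nc))
  )

  # node coordinates of constrained dofs, for the affine boundary field
  cnode_x <- (ix * 1)[boundary_node]
  cnode_y <- (iy * 1)[boundary_node]

  # centroid strain-displacement operator (element-size aware)
  B0 <- bmat_square(0, 0, element_size)

  env <- new.env(parent = emptyenv())
  env$sym <- NULL # symbolic factorization, filled lazily

  # precomputed gathers for the numeric assembly: per-triplet unit-stiffness
  # values and the last triplet index of each matrix slot (triplets are
  # already sorted by slot, so grouped sums reduce to diff-of-cumsum)
  kff_vals <- kevec[ff_k]
  ends_ff <- which(c(posff[-1] != posff[-length(posff)], TRUE))
  kfc_vals <- kevec[fc_k]
  ends_fc <- which(c(posfc[-1] != posfc[-length(posfc)], TRUE))

  structure(list(
    nx = nx, ny = ny, poisson = poisson, element_size = element_size,
    nel = nel, ndof = ndof, nf = nf,
    kevec = kevec, dofmat = dofmat,
    free = free, constrained = constrained,
    Kff = Kff, ff_e = ff_e, kff_vals = kff_vals, ends_ff = ends_ff,
    Kfc = Kfc, fc_e = fc_e, kfc_vals = kfc_vals, ends_fc = ends_fc,
    cnode_x = cnode_x, cnode_y = cnode_y,
    B0 = B0, cache = env
  ), class = "grid_solver")
}

# Numeric assembly of Kff / Kfc for a given element modulus vector
# (element-major: ex fastest). Returns the solver with updated matrices.
assemble_grid <- function(gs, evec) {
  cs <- cumsum(gs$kff_vals * evec[gs$ff_e])
  gs$Kff@x <- diff(c(0, cs[gs$ends_ff]))
  cs <- cumsum(gs$kfc_vals * evec[gs$fc_e])
  gs$Kfc@x <- diff(c(0, cs[gs$ends_fc]))
  gs
}

# Modulus matrix (ny x nx, row i = y band i) -> element-major vector.
modulus_to_evec <- function(modulus) {
  as.vector(t(modulus)) # ex fastest within each ey
}

#' Solve one macroscopic load case on a voxel plane-stress model
#'
#' Imposes the affine displacement field `u(x) = eps_bar x` on every boundary
#' node, where `eps_bar` is the macroscopic strain tensor of the load case
#' (kinematic uniform boundary conditions), solves the sparse linear system,
#' and returns the area-weighted mean of the element-centroid stresses over
#' the whole domain, floor-stiffness void elements included.
#'
#' @param model a [plane_stress_model()].
#' @param case a [load_case()].
#' @return a list with components `sigma_x`, `sigma_y`, `tau_xy` (MPa),
#'   of class `stress_state`.
#' @export
solve_case <- function(model, case) {
  stopifnot(inherits(model, "plane_stress_model"), inherits(case, "load_case"))
  res <- solve_cases_internal(model, list(case))
  res[[1]]
}

# Shared path: factor once, solve several load cases.
solve_cases_internal <- function(model, cases, gs = NULL) {
  ny <- nrow(model$modulus)
  nx <- ncol(model$modulus)
  if (is.null(gs)) {
    gs <- grid_solver(nx, ny, model$poisson, model$element_size)
  }
  evec <- modulus_to_evec(model$modulus)
  gs <- assemble_grid(gs, evec)

  if (is.null(gs$cache$sym)) {
    gs$cache$sym <- Matrix::Cholesky(gs$Kff, LDL = FALSE, super = TRUE)
  }
  ch <- Matrix::update(gs$cache$sym, gs$Kff)

  h <- model$element_size
  xs <- gs$cnode_x * h
  ys <- gs$cnode_y * h
  nc <- length(xs)

  UC <- matrix(0, nc * 2L, length(cases))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    # affine field u = eps_bar x with engineering shear split symmetrically
    ux <- cs$eps_x * xs + (cs$gamma_xy / 2) * ys
    uy <- (cs$gamma_xy / 2) * xs + cs$eps_y * ys
    UC[seq(1, 2 * nc, 2), k] <- ux
    UC[seq(2, 2 * nc, 2), k] <- uy
  }
  RHS <- -(gs$Kfc %*% UC)
  UF <- as.matrix(Matrix::solve(ch, RHS, system = "A"))

  nu <- model$poisson
  D <- matrix(c(
    1, nu, 0,
    nu, 1, 0,
    0, 0, (1 - nu) / 2
  ), 3, 3, byrow = TRUE) / (1 - nu^2)
  B0t <- t(gs$B0)

  out <- vector("list", length(cases))
  u <- numeric(gs$ndof)
  for (k in seq_along(cases)) {
    u[gs$free] <- UF[, k]
    u[gs$constrained] <- UC[, k]
    Ue <- matrix(u[gs$dofmat], nrow = gs$nel)
    strains <- Ue %*% B0t # nel x 3
    stresses <- (strains %*% t(D)) * evec # per-element centroid stress
    m <- colMeans(stresses)
    out[[k]] <- structure(
      list(sigma_x = m[1], sigma_y = m[2], tau_xy = m[3]),
      class = "stress_state"
    )
  }
  out
}

#' Plane-stress elasticity matrix
#'
#' Container for the six independent constants of the symmetric 3x3
#' plane-stress stiffness relating (sigma_x, sigma_y, tau_xy) to
#' (eps_x, eps_y, gamma_xy), in MPa.
#'
#' @param c11,c12,c13,c22,c23,c33 elastic constants in MPa.
#' @param c21 optional redundant measurement of the (2,1) entry (from the
#'   second load case); defaults to `c12`. Kept for the symmetry diagnostic.
#' @return object of class `elasticity_matrix`.
#' @export
elasticity_matrix <- function(c11, c12, c13, c22, c23, c33, c21 = c12) {
  stopifnot(is.finite(c(c11, c12, c13, c22, c23, c33)))
  structure(
    list(c11 = c11, c12 = c12, c13 = c13, c22 = c22, c23 = c23, c33 = c33,
         c21 = c21),
    class = "elasticity_matrix"
  )
}

#' @export
print.elasticity_matrix <- function(x, ...) {
  m <- as.matrix(x)
  cat("elasticity_matrix (MPa):\n")
  print(round(m, 2))
  invisible(x)
}

#' @export
as.matrix.elasticity_matrix <- function(x, ...) {
  matrix(c(
    x$c11, x$c12, x$c13,
    x$c12, x$c22, x$c23,
    x$c13, x$c23, x$c33
  ), 3, 3, byrow = TRUE)
}

# Elasticity matrix of a homogeneous plane-stress plate (closed form).
#' Closed-form elasticity matrix of a homogeneous plate
#'
#' @param e Young's modulus (MPa); @param poisson Poisson's ratio.
#' @return an [elasticity_matrix()].
#' @export
plate_elasticity <- function(e, poisson) {
  nu <- poisson
  elasticity_matrix(
    c11 = e / (1 - nu^2), c12 = nu * e / (1 - nu^2), c13 = 0,
    c22 = e / (1 - nu^2), c23 = 0, c33 = e / (2 * (1 + nu))
  )
}

#' Homogenize a voxel plane-stress model
#'
#' Runs the three canonical loading scenarios (uniaxial compression along x,
#' uniaxial compression along y, in-plane shear) under kinematic uniform
#' boundary conditions and forms the effective elasticity matrix from the
#' domain-averaged stresses: case 1 gives c11 = sigma_x/eps_x,
#' c12 = sigma_y/eps_x, c13 = tau_xy/eps_x; case 2 gives c22, c23 (and a
#' redundant c21 used as a symmetry diagnostic); case 3 gives
#' c33 = tau_xy/gamma_xy.
#'
#' @param model a [plane_stress_model()].
#' @param magnitude applied strain magnitude (default 0.1; the response is
#'   linear so the value only rescales intermediate displacements).
#' @param solver optional reusable solver from [grid_solver()] for repeated
#'   calls on same-shaped grids.
#' @return an [elasticity_matrix()].
#' @export
homogenize <- function(model, magnitude = 0.1, solver = NULL) {
  stopifnot(inherits(model, "plane_stress_model"))
  if (!(magnitude > 0)) stop("magnitude must be > 0")
  m <- magnitude
  cases <- list(
    load_case(eps_x = -m),
    load_case(eps_y = -m),
    load_case(gamma_xy = +m)
  )
  st <- solve_cases_internal(model, cases, gs = solver)
  s1 <- st[[1]]; s2 <- st[[2]]; s3 <- st[[3]]
  elasticity_matrix(
    c11 = s1$sigma_x / (-m),
    c12 = s1$sigma_y / (-m),
    c13 = s1$tau_xy / (-m),
    c22 = s2$sigma_y / (-m),
    c23 = s2$tau_xy / (-m),
    c33 = s3$tau_xy / (+m),
    c21 = s2$sigma_x / (-m)
  )
}
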