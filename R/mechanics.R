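#' Mechanical constants of the tissue box
#'
#' Fixed constitutive and coupling constants of the mechanically coupled
#' model: homogeneous Young's modulus `E` (kPa) and Poisson's ratio `nu` of
#' breast tissue, the tumor-induced solid stress magnitude `gN` (kPa), the
#' Winkler foundation constant `kw` (kPa/mm) of the elastic boundary
#' support, the stress-diffusivity coupling `gammaN` (1/kPa), and the
#' carrying capacity `theta` (cells/mm^3). The Lame parameters follow as
#' `lambda = E*nu/((1+nu)(1-2nu))` and `mu = E/(2(1+nu))`.
#'
#' @param E Young's modulus (kPa).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param gN Tumor-induced solid stress (kPa).
#' @param kw Winkler constant (kPa/mm).
#' @param gammaN Stress-diffusivity coupling (1/kPa).
#' @param theta Carrying capacity (cells/mm^3).
#' @return An object of class `mech_constants`.
#' @export
mech_constants <- function(E = 3, nu = 0.45, gN = 5, kw = 0.20,
                           gammaN = 2.5, theta = THETA_DEFAULT) {
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)", call. = FALSE)
  if (any(c(E, gN, kw, theta) <= 0)) {
    stop("E, gN, kw and theta must be positive", call. = FALSE)
  }
  if (gammaN < 0) {
    stop("gammaN must be non-negative (0 decouples mechanics)", call. = FALSE)
  }
  structure(
    list(E = E, nu = nu, gN = gN, kw = kw, gammaN = gammaN, theta = theta,
         lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
         mu = E / (2 * (1 + nu))),
    class = "mech_constants"
  )
}

# --- trilinear hexahedral element matrices -------------------------------
#
# Reference matrices for a uniform hexahedron of spacing h: the volumetric
# (lambda) stiffness, the deviatoric/shear (mu) stiffness, and the
# divergence load coupling int phi_b dphi_a/dx_c. The lambda term uses
# single-point (reduced) quadrature, the standard remedy for volumetric
# locking at nearly incompressible Poisson ratios; everything else uses full
# 2x2x2 Gauss quadrature.
hex_element_matrices <- function(h) {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  detJ <- prod(h) / 8
  eval_basis <- function(xi) {
    phi <- numeric(8)
    dphi <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- 2 * corners[a, ] - 1
      f <- (1 + s * xi) / 2
      phi[a] <- prod(f)
      for (c in 1:3) {
        ff <- f
        ff[c] <- s[c] / 2
        dphi[a, c] <- prod(ff) * 2 / h[c]
      }
    }
    list(phi = phi, dphi = dphi)
  }
  Ke_lam <- matrix(0, 24, 24)
  Ke_mu <- matrix(0, 24, 24)
  Be <- matrix(0, 24, 8)
  gp <- 1 / sqrt(3) * c(-1, 1)
  for (gx in gp) for (gy in gp) for (gz in gp) {
    b <- eval_basis(c(gx, gy, gz))
    Bs <- matrix(0, 6, 24)
    for (a in 1:8) {
      ia <- 3 * (a - 1)
      Bs[1, ia + 1] <- b$dphi[a, 1]
      Bs[2, ia + 2] <- b$dphi[a, 2]
      Bs[3, ia + 3] <- b$dphi[a, 3]
      Bs[4, ia + 1] <- b$dphi[a, 2]; Bs[4, ia + 2] <- b$dphi[a, 1]
      Bs[5, ia + 2] <- b$dphi[a, 3]; Bs[5, ia + 3] <- b$dphi[a, 2]
      Bs[6, ia + 1] <- b$dphi[a, 3]; Bs[6, ia + 3] <- b$dphi[a, 1]
    }
    Dm <- diag(c(2, 2, 2, 1, 1, 1))
    Ke_mu <- Ke_mu + detJ * t(Bs) %*% Dm %*% Bs
    for (a in 1:8) for (c in 1:3) for (bb in 1:8) {
      Be[3 * (a - 1) + c, bb] <- Be[3 * (a - 1) + c, bb] +
        detJ * b$dphi[a, c] * b$phi[bb]
    }
  }
  # reduced (1-point) quadrature for the volumetric term
  b0 <- eval_basis(c(0, 0, 0))
  Bvol <- numeric(24)
  for (a in 1:8) for (c in 1:3) Bvol[3 * (a - 1) + c] <- b0$dphi[a, c]
  Ke_lam <- 8 * detJ * outer(Bvol, Bvol)
  list(Ke_lam = Ke_lam, Ke_mu = Ke_mu, Be = Be)
}

# bilinear face mass matrix for a rectangle a x b, cyclic node order
face_mass_matrix <- function(a, b) {
  (a * b / 36) * matrix(c(4, 2, 1, 2,
                          2, 4, 2, 1,
                          1, 2, 4, 2,
                          2, 1, 2, 4), 4, 4)
}

# Assemble the mechanics operators for a grid: the stiffness matrix K
# (elastic stiffness + Winkler boundary mass, symmetric positive definite),
# its cached Cholesky factorization, the load coupling B (nodal density ->
# nodal force, before the gN/theta scale), and sparse central-difference
# gradient operators used for stress recovery. Nodes coincide with voxel
# centres; elements are the (n-1)^3 cells between them.
assemble_mechanics <- function(grid, consts) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  h <- grid$spacing
  n <- nx * ny * nz
  ref <- hex_element_matrices(h)
  Ke <- consts$lambda * ref$Ke_lam + consts$mu * ref$Ke_mu

  node_id <- function(i, j, k) i + nx * (j - 1) + nx * ny * (k - 1)
  el <- expand.grid(i = 1:(nx - 1), j = 1:(ny - 1), k = 1:(nz - 1))
  conn <- matrix(0L, nrow(el), 8)
  a <- 1
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    conn[, a] <- node_id(el$i + dx, el$j + dy, el$k + dz)
    a <- a + 1
  }
  dofs <- matrix(0L, nrow(el), 24)
  for (a in 1:8) for (c in 1:3) dofs[, 3 * (a - 1) + c] <- 3L * (conn[, a] - 1L) + c

  idx_r <- rep(1:24, times = 24)
  idx_c <- rep(1:24, each = 24)
  I <- as.vector(t(dofs[, idx_r]))
  J <- as.vector(t(dofs[, idx_c]))
  X <- rep(Ke[cbind(idx_r, idx_c)], times = nrow(el))
  K <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(3 * n, 3 * n))

  add_winkler <- function(K, nodes4, Mf) {
    Iw <- Jw <- Xw <- NULL
    mf <- Mf[cbind(rep(1:4, times = 4), rep(1:4, each = 4))]
    for (c in 1:3) {
      d4 <- 3L * (nodes4 - 1L) + c
      Iw <- c(Iw, as.vector(t(d4[, rep(1:4, times = 4)])))
      Jw <- c(Jw, as.vector(t(d4[, rep(1:4, each = 4)])))
      Xw <- c(Xw, rep(mf, times = nrow(d4)))
    }
    K + Matrix::sparseMatrix(i = Iw, j = Jw, x = consts$kw * Xw, dims = dim(K))
  }
  fjk <- expand.grid(j = 1:(ny - 1), k = 1:(nz - 1))
  for (ii in c(1L, nx)) {
    q <- cbind(node_id(ii, fjk$j, fjk$k), node_id(ii, fjk$j + 1, fjk$k),
               node_id(ii, fjk$j + 1, fjk$k + 1), node_id(ii, fjk$j, fjk$k + 1))
    K <- add_winkler(K, q, face_mass_matrix(h[2], h[3]))
  }
  fik <- expand.grid(i = 1:(nx - 1), k = 1:(nz - 1))
  for (jj in c(1L, ny)) {
    q <- cbind(node_id(fik$i, jj, fik$k), node_id(fik$i + 1, jj, fik$k),
               node_id(fik$i + 1, jj, fik$k + 1), node_id(fik$i, jj, fik$k + 1))
    K <- add_winkler(K, q, face_mass_matrix(h[1], h[3]))
  }
  fij <- expand.grid(i = 1:(nx - 1), j = 1:(ny - 1))
  for (kk in c(1L, nz)) {
    q <- cbind(node_id(fij$i, fij$j, kk), node_id(fij$i + 1, fij$j, kk),
               node_id(fij$i + 1, fij$j + 1, kk), node_id(fij$i, fij$j + 1, kk))
    K <- add_winkler(K, q, face_mass_matrix(h[1], h[2]))
  }

  Iw <- as.vector(t(dofs[, rep(1:24, times = 8)]))
  Jw <- as.vector(t(conn[, rep(1:8, each = 24)]))
  Xw <- rep(ref$Be[cbind(rep(1:24, times = 8), rep(1:8, each = 24))],
            times = nrow(el))
  B <- Matrix::sparseMatrix(i = Iw, j = Jw, x = Xw, dims = c(3 * n, n))

  # nodal central-difference gradient operators (one-sided at the faces)
  grad_1d <- function(m, hh) {
    if (m < 2) stop("grid too small for gradients")
    i <- c(1, 1, rep(2:(m - 1), each = 2), m, m)
    j <- c(1, 2, as.vector(rbind(1:(m - 2), 3:m)), m - 1, m)
    x <- c(-1, 1, rep(c(-0.5, 0.5), m - 2), -1, 1) / hh
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, m))
  }
  Ix <- Matrix::Diagonal(nx); Iy <- Matrix::Diagonal(ny); Iz <- Matrix::Diagonal(nz)
  Gx <- Matrix::kronecker(Iz, Matrix::kronecker(Iy, grad_1d(nx, h[1])))
  Gy <- Matrix::kronecker(Iz, Matrix::kronecker(grad_1d(ny, h[2]), Ix))
  Gz <- Matrix::kronecker(grad_1d(nz, h[3]), Matrix::kronecker(Iy, Ix))

  K <- Matrix::forceSymmetric(K)
  list(
    K = K,
    chol = Matrix::Cholesky(K, LDL = FALSE, super = TRUE),
    B = B,
    Gx = Gx, Gy = Gy, Gz = Gz,
    n = n, grid = grid, consts = consts
  )
}

.mech_cache <- new.env(parent = emptyenv())

mechanics_operators <- function(grid, consts) {
  key <- digest::digest(list(grid$shape, grid$spacing, consts$E, consts$nu,
                             consts$kw))
  if (is.null(.mech_cache[[key]])) {
    .mech_cache[[key]] <- assemble_mechanics(grid, consts)
  }
  .mech_cache[[key]]
}

# stress components from displacement matrix U (3n x m, dofs interleaved
# x,y,z per node) and density matrix Nmat (n x m); returns list of six
# n x m matrices s11, s22, s33, s12, s23, s13
stress_from_displacement <- function(ops, U, Nmat) {
  n <- ops$n
  cst <- ops$consts
  ux <- U[seq(1, 3 * n, by = 3), , drop = FALSE]
  uy <- U[seq(2, 3 * n, by = 3), , drop = FALSE]
  uz <- U[seq(3, 3 * n, by = 3), , drop = FALSE]
  dxx <- as.matrix(ops$Gx %*% ux)
  dyy <- as.matrix(ops$Gy %*% uy)
  dzz <- as.matrix(ops$Gz %*% uz)
  div <- dxx + dyy + dzz
  growth <- cst$gN * Nmat / cst$theta
  list(
    s11 = cst$lambda * div + 2 * cst$mu * dxx - growth,
    s22 = cst$lambda * div + 2 * cst$mu * dyy - growth,
    s33 = cst$lambda * div + 2 * cst$mu * dzz - growth,
    s12 = cst$mu * as.matrix(ops$Gy %*% ux + ops$Gx %*% uy),
    s23 = cst$mu * as.matrix(ops$Gz %*% uy + ops$Gy %*% uz),
    s13 = cst$mu * as.matrix(ops$Gz %*% ux + ops$Gx %*% uz)
  )
}

von_mises_from_components <- function(s) {
  v <- s$s11^2 + s$s22^2 + s$s33^2 -
    s$s11 * s$s22 - s$s22 * s$s33 - s$s11 * s$s33 +
    3 * (s$s12^2 + s$s23^2 + s$s13^2)
  v[v < 0] <- 0 # guard rounding of exactly hydrostatic states
  sqrt(v)
}

#' Quasistatic mechanical equilibrium under tumor-induced stress
#'
#' Solves the linear elastic equilibrium of the tissue box loaded by the
#' tumor-induced solid stress (proportional to the normalized tumor cell
#' density) with Winkler elastic-foundation boundary conditions on all six
#' box faces. The discretization uses trilinear hexahedral finite elements
#' on the voxel lattice with selective reduced integration of the
#' volumetric term; the symmetric positive definite system is solved by a
#' cached sparse Cholesky factorization (the factor depends only on the
#' grid and elastic constants, so repeated solves with evolving density
#' reuse it).
#'
#' @param N A [scalar_field()] of tumor cell density in `[0, theta]`.
#' @param consts A [mech_constants()] object.
#' @return An object of class `mech_state`: list with `u` (displacement,
#'   `n x 3` matrix, mm), `sigma` (list of six nodal stress component
#'   arrays, kPa), `sigma_v` (von Mises stress [scalar_field()], kPa), and
#'   the relative residual of the linear solve.
#' @export
solve_equilibrium <- function(N, consts = mech_constants()) {
  stopifnot(inherits(N, "scalar_field"))
  if (any(N$values < 0) || any(N$values > consts$theta * (1 + 1e-12))) {
    stop("density must lie within [0, theta]", call. = FALSE)
  }
  ops <- mechanics_operators(N$grid, consts)
  nv <- matrix(as.vector(N$values), ncol = 1)
  f <- (consts$gN / consts$theta) * (ops$B %*% nv)
  u <- Matrix::solve(ops$chol, f)
  res <- as.numeric(sqrt(sum((ops$K %*% u - f)^2)))
  fn <- sqrt(sum(f^2))
  rel <- if (fn > 0) res / fn else 0
  if (!is.finite(rel) || rel > 1e-8) {
    stop(sprintf("mechanics solve failed: relative residual %.3e", rel),
         call. = FALSE)
  }
  U <- as.matrix(u)
  s <- stress_from_displacement(ops, U, nv)
  sv <- von_mises_from_components(s)
  n <- ops$n
  structure(
    list(
      u = cbind(U[seq(1, 3 * n, 3), 1], U[seq(2, 3 * n, 3), 1],
                U[seq(3, 3 * n, 3), 1]),
      sigma = lapply(s, function(m) array(m[, 1], dim = N$grid$shape)),
      sigma_v = scalar_field(N$grid, array(sv[, 1], dim = N$grid$shape)),
      residual = rel
    ),
    class = "mech_state"
  )
}

#' Von Mises stress of a symmetric stress tensor field
#'
#' Computes the scalar deviatoric stress invariant voxelwise from the six
#' independent components of a symmetric stress tensor.
#'
#' @param sigma A list with arrays (or scalars) `s11`, `s22`, `s33`, `s12`,
#'   `s23`, `s13`, or a `mech_state` whose `sigma` is used.
#' @return An array (or scalar) of non-negative von Mises stress.
#' @examples
#' von_mises(list(s11 = 2, s22 = 2, s33 = 2, s12 = 0, s23 = 0, s13 = 0)) # 0
#' @export
von_mises <- function(sigma) {
  if (inherits(sigma, "mech_state")) sigma <- sigma$sigma
  stopifnot(all(c("s11", "s22", "s33", "s12", "s23", "s13") %in% names(sigma)))
  von_mises_from_components(sigma)
}

#' Stress-inhibited tumor cell diffusivity
#'
#' Maps the von Mises stress field to the local tumor cell diffusivity
#' `D = D0 * exp(-gammaN * sigma_v)`: mechanical stress exponentially
#' inhibits tumor cell mobility, so `0 < D <= D0` everywhere.
#'
#' @param D0 Baseline diffusivity (mm^2/day, positive).
#' @param sigma_v Non-negative von Mises stress: array, scalar, or
#'   [scalar_field()].
#' @param gammaN Coupling constant (1/kPa).
#' @return Diffusivity with the same shape as `sigma_v`.
#' @export
diffusivity <- function(D0, sigma_v, gammaN = 2.5) {
  if (D0 <= 0) stop("D0 must be positive", call. = FALSE)
  as_field <- inherits(sigma_v, "scalar_field")
  v <- if (as_field) sigma_v$values else sigma_v
  if (any(v < 0)) stop("sigma_v must be non-negative", call. = FALSE)
  out <- D0 * exp(-gammaN * v)
  if (as_field) scalar_field(sigma_v$grid, out) else out
}
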