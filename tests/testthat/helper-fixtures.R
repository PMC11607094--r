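# Shared fixtures for the suite: small scenarios built in code, a reference
# R-only implicit reaction-diffusion stepper (independent of the compiled
# kernel), and a lazily computed cache for the expensive campaign results
# shared between acceptance blocks.

tiny_grid <- function(n = 8, h = 4) make_grid(rep(n, 3), rep(h, 3))

tiny_scenario <- function(perfusion = "well", seed = 1) {
  synth_scenario(tiny_grid(), tumor_radius_mm = 5, perfusion = perfusion,
                 seed = seed)
}

study_scenario <- function(perfusion = "well", seed = 1) {
  synth_scenario(make_grid(c(16, 16, 16), c(2, 2, 2)), tumor_radius_mm = 8,
                 perfusion = perfusion, seed = seed)
}

# Independent backward-Euler reference for dN/dt = div(D grad N) + rho N
# (1 - N/theta): assembles the conservative stencil as a sparse matrix and
# runs damped Newton with a direct sparse solve. Used as the dual route
# against the compiled kernel.
reference_rd_steps <- function(N0, Dfield, rho, dt, nsteps, theta) {
  g <- N0$grid
  shp <- g$shape
  n <- prod(shp)
  vox <- function(i, j, k) i + shp[1] * (j - 1L) + shp[1] * shp[2] * (k - 1L)
  dv <- as.vector(if (inherits(Dfield, "scalar_field")) Dfield$values else
    array(Dfield, dim = shp))
  rv <- as.vector(if (inherits(rho, "scalar_field")) rho$values else
    array(rho, dim = shp))
  ii <- jj <- xx <- NULL
  add_faces <- function(lo, hi, h2) {
    dface <- 0.5 * (dv[lo] + dv[hi]) / h2
    ii <<- c(ii, lo, hi, lo, hi)
    jj <<- c(jj, hi, lo, lo, hi)
    xx <<- c(xx, dface, dface, -dface, -dface)
  }
  fx <- expand.grid(i = 1:(shp[1] - 1), j = 1:shp[2], k = 1:shp[3])
  add_faces(vox(fx$i, fx$j, fx$k), vox(fx$i + 1, fx$j, fx$k), g$spacing[1]^2)
  fy <- expand.grid(i = 1:shp[1], j = 1:(shp[2] - 1), k = 1:shp[3])
  add_faces(vox(fy$i, fy$j, fy$k), vox(fy$i, fy$j + 1, fy$k), g$spacing[2]^2)
  fz <- expand.grid(i = 1:shp[1], j = 1:shp[2], k = 1:(shp[3] - 1))
  add_faces(vox(fz$i, fz$j, fz$k), vox(fz$i, fz$j, fz$k + 1), g$spacing[3]^2)
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Nv <- as.vector(N0$values)
  I <- Matrix::Diagonal(n)
  for (s in seq_len(nsteps)) {
    Nn <- Nv
    for (it in 1:50) {
      FF <- Nn - Nv - dt * as.vector(L %*% Nn) - dt * rv * Nn * (1 - Nn / theta)
      if (sqrt(sum(FF^2)) <= 1e-12 * max(sqrt(sum(Nv^2)), 1)) break
      J <- I - dt * L - Matrix::Diagonal(n, dt * rv * (1 - 2 * Nn / theta))
      Nn <- Nn + as.vector(Matrix::solve(J, -FF))
    }
    Nv <- Nn
  }
  scalar_field(g, array(Nv, dim = shp))
}

# campaign cache shared across acceptance blocks (computed at most once per
# test run)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_sa <- function(kind) {
  key <- paste0("sa_", kind)
  if (is.null(.acceptance_cache[[key]])) {
    sc <- study_scenario()
    .acceptance_cache[[key]] <- run_sa(
      sc, kind, n_s = 128, seed = 1,
      keep_final_density = (kind == "dox_cyc")
    )
  }
  .acceptance_cache[[key]]
}
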