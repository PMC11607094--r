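test_that("von Mises invariant vanishes for hydrostatic states", {
  s <- 3.7
  hydro <- list(s11 = s, s22 = s, s33 = s, s12 = 0, s23 = 0, s13 = 0)
  # zero up to the floating cancellation of the squared terms
  expect_lt(von_mises(hydro), 1e-6 * s)
  uni <- list(s11 = -s, s22 = 0, s33 = 0, s12 = 0, s23 = 0, s13 = 0)
  expect_equal(von_mises(uni), abs(s))
  shear <- list(s11 = 0, s22 = 0, s33 = 0, s12 = s, s23 = 0, s13 = 0)
  expect_equal(von_mises(shear), sqrt(3) * abs(s))
})

test_that("stress-inhibited diffusivity follows the exponential law", {
  expect_equal(diffusivity(2e-4, 0), 2e-4)
  expect_equal(diffusivity(2e-4, log(2) / 2.5, gammaN = 2.5), 1e-4)
  sv <- seq(0, 5, by = 0.25)
  d <- diffusivity(0.1, sv)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d <= 0.1))
  expect_error(diffusivity(0, 1), "positive")
  expect_error(diffusivity(1, -1), "non-negative")
})

test_that("zero density gives the stress-free state", {
  g <- tiny_grid()
  ms <- solve_equilibrium(scalar_field(g, 0))
  expect_equal(max(abs(ms$u)), 0)
  expect_equal(max(ms$sigma_v$values), 0)
  expect_true(all(vapply(ms$sigma, function(a) max(abs(a)), numeric(1)) == 0))
})

test_that("equilibrium is linear in the density load", {
  sc <- tiny_scenario()
  half <- scalar_field(sc$grid, sc$N0$values / 2)
  m1 <- solve_equilibrium(half)
  m2 <- solve_equilibrium(sc$N0)
  expect_equal(m2$u, 2 * m1$u, tolerance = 1e-9)
  expect_equal(m2$sigma_v$values, 2 * m1$sigma_v$values, tolerance = 1e-9)
})

test_that("a density bump pushes the surrounding tissue outward", {
  g <- make_grid(c(12, 12, 12), 2)
  ax <- grid_axes(g)
  ctr <- vapply(ax, function(a) mean(range(a)), numeric(1))
  r2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+"),
              (ax$z - ctr[3])^2, "+")
  N <- scalar_field(g, THETA_DEFAULT * 0.6 * exp(-r2 / 30))
  ms <- solve_equilibrium(N)
  # radial component of u on a probe shell
  pos <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  rad <- sweep(pos, 2, ctr)
  rn <- sqrt(rowSums(rad^2))
  shell <- which(rn > 6 & rn < 10)
  u <- ms$u[, c(1, 2, 3)]
  radial <- rowSums(u[shell, ] * rad[shell, ]) / rn[shell]
  expect_true(all(radial > 0))
})

test_that("the assembled operator is symmetric and nonsingular", {
  g <- tiny_grid()
  ops <- nacdyn:::mechanics_operators(g, mech_constants())
  expect_lt(max(abs(ops$K - Matrix::t(ops$K))), 1e-14)
  # random loads are solved to tight residual (Winkler pins rigid modes)
  f <- withr::with_seed(5, rnorm(nrow(ops$K)))
  u <- Matrix::solve(ops$chol, f)
  expect_lt(sqrt(sum((ops$K %*% u - f)^2)) / sqrt(sum(f^2)), 1e-10)
})

test_that("displacements self-converge at second order under refinement", {
  # same physical box and a smooth density on three nested grids
  L <- 24
  shapes <- c(7, 13, 25)
  sols <- lapply(shapes, function(nn) {
    g <- make_grid(rep(nn, 3), rep(L / (nn - 1), 3))
    ax <- grid_axes(g)
    r2 <- outer(outer((ax$x - L / 2)^2, (ax$y - L / 2)^2, "+"),
                (ax$z - L / 2)^2, "+")
    N <- scalar_field(g, THETA_DEFAULT * 0.5 * exp(-r2 / 28))
    solve_equilibrium(N)
  })
  # compare displacement magnitude at the shared coarse nodes
  at_coarse <- function(ms, stride, nn) {
    n <- nn^3
    um <- sqrt(rowSums(ms$u^2))
    arr <- array(um, dim = rep(nn, 3))
    idx <- seq(1, nn, by = stride)
    arr[idx, idx, idx]
  }
  u1 <- at_coarse(sols[[1]], 1, 7)
  u2 <- at_coarse(sols[[2]], 2, 13)
  u3 <- at_coarse(sols[[3]], 4, 25)
  e1 <- sqrt(mean((u1 - u3)^2))
  e2 <- sqrt(mean((u2 - u3)^2))
  order <- log2(e1 / e2)
  expect_gt(order, 1.5)
})

test_that("compiled and R stress recovery agree on a chunk", {
  sc <- tiny_scenario()
  consts <- mech_constants()
  ops <- nacdyn:::mechanics_operators(sc$grid, consts)
  nv <- matrix(as.vector(sc$N0$values), ncol = 1)
  f <- (consts$gN / consts$theta) * (ops$B %*% nv)
  U <- as.matrix(Matrix::solve(ops$chol, f))
  svR <- nacdyn:::von_mises_from_components(
    nacdyn:::stress_from_displacement(ops, U, nv)
  )
  svC <- nacdyn:::von_mises_u_cpp(U, nv, sc$grid$shape, sc$grid$spacing,
                                  consts$lambda, consts$mu,
                                  consts$gN / consts$theta)
  expect_equal(as.vector(svC), as.vector(svR), tolerance = 1e-12)
})
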