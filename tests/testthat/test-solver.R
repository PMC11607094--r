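test_that("pure diffusion conserves total mass to solver tolerance", {
  sc <- tiny_scenario()
  D <- scalar_field(sc$grid, 0.08)
  N <- sc$N0
  m0 <- total_cells(N)
  for (s in 1:8) {
    N <- step(N, D, 0, dt = 0.25)
    expect_lt(abs(total_cells(N) - m0) / m0, 1e-8)
  }
  # and the profile actually diffuses
  expect_lt(max(N$values), max(sc$N0$values))
})

test_that("reaction-only stepping matches the closed-form logistic", {
  sc <- tiny_scenario()
  theta <- sc$theta
  rho <- 0.05
  exact <- function(n0, t) theta * n0 / (n0 + (theta - n0) * exp(-rho * t))
  for (dt in c(0.5, 0.25, 0.125)) {
    N <- sc$N0
    nsteps <- round(4 / dt)
    for (s in seq_len(nsteps)) N <- step(N, 0, rho, dt = dt, theta = theta)
    err <- max(abs(N$values - exact(sc$N0$values, 4))) / theta
    # backward Euler: first-order accuracy
    expect_lt(err, 0.1 * dt)
    assign(paste0("err_", dt), err, envir = environment())
  }
  # halving dt roughly halves the error
  expect_gt(err_0.5 / err_0.25, 1.6)
  expect_gt(err_0.25 / err_0.125, 1.6)
})

test_that("the carrying capacity is a fixed point", {
  g <- tiny_grid()
  N <- scalar_field(g, THETA_DEFAULT)
  N2 <- step(N, scalar_field(g, 0.05), 0.1, dt = 0.25)
  expect_equal(N2$values, N$values, tolerance = 1e-12)
})

test_that("stepping agrees with an independent sparse-matrix reference", {
  sc <- tiny_scenario()
  D <- scalar_field(sc$grid, array(
    0.05 * (1 + as.vector(sc$p$values)), dim = sc$grid$shape
  ))
  rho <- scalar_field(sc$grid, array(
    0.04 - 0.1 * as.vector(sc$p$values), dim = sc$grid$shape
  ))
  N_kernel <- sc$N0
  for (s in 1:4) N_kernel <- step(N_kernel, D, rho, dt = 0.25)
  N_ref <- reference_rd_steps(sc$N0, D, rho, dt = 0.25, nsteps = 4,
                              theta = sc$theta)
  expect_lt(max(abs(N_kernel$values - N_ref$values)) / sc$theta, 1e-9)
})

test_that("spatial error of the diffusion stencil drops at second order", {
  # fixed dt; compare pure-diffusion solutions on nested grids so the
  # (identical) temporal error cancels in the differences
  L <- 24
  shapes <- c(7, 13, 25)
  runs <- lapply(shapes, function(nn) {
    g <- make_grid(rep(nn, 3), rep(L / (nn - 1), 3))
    ax <- grid_axes(g)
    r2 <- outer(outer((ax$x - L / 2)^2, (ax$y - L / 2)^2, "+"),
                (ax$z - L / 2)^2, "+")
    N <- scalar_field(g, 1e6 * exp(-r2 / 20))
    for (s in 1:8) N <- step(N, 2, 0, dt = 0.25, theta = THETA_DEFAULT)
    N
  })
  sub <- function(N, stride, nn) {
    idx <- seq(1, nn, by = stride)
    N$values[idx, idx, idx]
  }
  u1 <- sub(runs[[1]], 1, 7)
  u2 <- sub(runs[[2]], 2, 13)
  u3 <- sub(runs[[3]], 4, 25)
  e1 <- sqrt(mean((u1 - u3)^2))
  e2 <- sqrt(mean((u2 - u3)^2))
  expect_gt(log2(e1 / e2), 1.5)
})

test_that("full simulations are deterministic and bounded", {
  sc <- tiny_scenario()
  pars <- default_params("dox_cyc")
  t1 <- simulate(sc, pars, standard_regimen("dox_cyc"))
  t2 <- simulate(sc, pars, standard_regimen("dox_cyc"))
  expect_identical(t1$qoi, t2$qoi)
  expect_identical(t1$final$values, t2$final$values)
  expect_true(all(t1$final$values >= 0 & t1$final$values <= sc$theta))
})

test_that("density stays within [0, theta] across sampled parameter draws", {
  sc <- tiny_scenario()
  X <- lhs_sample(sa_parameter_space("dox_cyc"), 100, seed = 3)
  res <- nacdyn:::simulate_batch(sc, t(X), standard_regimen("dox_cyc"),
                                 keep_final = TRUE)
  expect_true(all(res$final >= 0))
  expect_true(all(res$final <= sc$theta * (1 + 1e-12)))
  expect_true(all(res$NT >= 0))
})

test_that("batched and single-run paths agree exactly", {
  sc <- tiny_scenario()
  X <- lhs_sample(sa_parameter_space("dox_cyc"), 3, seed = 9)
  reg <- standard_regimen("dox_cyc")
  res <- nacdyn:::simulate_batch(sc, t(X), reg, keep_final = TRUE)
  for (r in 1:3) {
    tr <- simulate(sc, params_from_vector(X[r, ]), reg)
    expect_equal(tr$qoi$VT, res$VT[, r])
    expect_equal(tr$qoi$NT, res$NT[, r])
    expect_equal(as.vector(tr$final$values), res$final[, r])
  }
})

test_that("a drug-free run with decoupled mechanics is pure reaction-diffusion", {
  sc <- tiny_scenario()
  mech0 <- mech_constants(gammaN = 0)
  pd <- pd_params(rho0 = 0.03, h1 = 1, h2 = 1, C1 = 1, C2 = 1, E1n = 0,
                  E2n = 0, a1 = 1, a2 = 1, beta = 0)
  pars <- model_params(D0 = 0.02, pd = pd, dmax1 = 0, dmax2 = 0,
                       gamma1 = 1, gamma2 = 1, mech = mech0)
  reg <- new_regimen(drug_spec("a", 0, 0, 1), drug_spec("b", 0, 0, 1),
                     horizon = 2, kind = "custom")
  tr <- simulate(sc, pars, reg, dt = 0.25)
  N_ref <- reference_rd_steps(sc$N0, 0.02, 0.03, dt = 0.25, nsteps = 8,
                              theta = sc$theta)
  expect_lt(max(abs(tr$final$values - N_ref$values)) / sc$theta, 1e-9)
})

test_that("strongly lethal drug exposure shrinks the tumor", {
  sc <- tiny_scenario()
  pd <- pd_params(rho0 = 0.05, h1 = 2, h2 = 1, C1 = 0.01, C2 = 1,
                  E1n = -5, E2n = 0, a1 = 1, a2 = 1, beta = 0)
  pars <- model_params(D0 = 1e-3, pd = pd, dmax1 = 500, dmax2 = 0,
                       gamma1 = 0.4, gamma2 = 1)
  tr <- simulate(sc, pars, standard_regimen("dox_cyc"))
  expect_lt(tr$qoi$NT[nrow(tr$qoi)], tr$qoi$NT[1])
})

test_that("snapshots are taken at the requested times", {
  sc <- tiny_scenario()
  reg <- standard_regimen("dox_cyc")
  tr <- simulate(sc, default_params("dox_cyc"), reg,
                 snapshot_times = c(0, 28, 56))
  expect_length(tr$snapshots, 3)
  expect_equal(tr$snapshots[["t=56"]]$values, tr$final$values)
  expect_equal(tr$snapshots[["t=0"]]$values, sc$N0$values)
})

test_that("trajectories persist to a plain-file directory", {
  sc <- tiny_scenario()
  tr <- simulate(sc, default_params("dox_cyc"), standard_regimen("dox_cyc"),
                 snapshot_times = 28)
  dir <- withr::local_tempdir()
  write_trajectory(tr, dir)
  expect_true(file.exists(file.path(dir, "qoi.csv")))
  qoi <- utils::read.csv(file.path(dir, "qoi.csv"))
  expect_equal(nrow(qoi), nrow(tr$qoi))
  expect_true(file.exists(file.path(dir, "final.nii.gz")))
  back <- read_volume(file.path(dir, "final.nii.gz"))
  expect_equal(back$values, tr$final$values)
})

test_that("invalid step inputs are rejected", {
  sc <- tiny_scenario()
  expect_error(step(sc$N0, 0.1, 0, dt = 0), "positive")
  expect_error(step(sc$N0, -0.1, 0, dt = 0.25), "non-negative")
  reg <- standard_regimen("dox_cyc")
  expect_error(simulate(sc, default_params("dox_cyc"), reg, dt = 0.3),
               "divisible")
})
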