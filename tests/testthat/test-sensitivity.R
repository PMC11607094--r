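test_that("parameter spaces carry the admissible ranges and scales", {
  for (kind in c("dox_cyc", "ptx_cpt")) {
    sp <- sa_parameter_space(kind)
    expect_equal(nrow(sp), 15)
    expect_equal(sp$name, PARAM_NAMES)
    expect_true(all(sp$scale %in% c("log", "regular")))
    expect_true(all(sp$lower < sp$upper))
    expect_true(all(sp$lower[sp$scale == "log"] > 0))
  }
  dox <- sa_parameter_space("dox_cyc")
  rng <- function(sp, nm) c(sp$lower[sp$name == nm], sp$upper[sp$name == nm])
  expect_equal(rng(dox, "E1n"), c(-5, 0.5))
  expect_equal(rng(dox, "gamma2"), c(1.7, 5.4))
  expect_equal(rng(dox, "D0"), c(1e-6, 1e-1))
  ptx <- sa_parameter_space("ptx_cpt")
  expect_equal(rng(ptx, "gamma2"), c(0.1, 0.2))
  expect_equal(rng(ptx, "E2n"), c(-3, 0.5))
  expect_equal(rng(ptx, "dmax1"), c(5, 1e3))
  expect_error(sa_parameter_space("other"))
})

test_that("midpoints are geometric on log scales and arithmetic otherwise", {
  sp <- sa_parameter_space("dox_cyc")
  mid <- space_midpoints(sp)
  expect_equal(mid[["D0"]], 10^((-6 + -1) / 2))
  expect_equal(mid[["E1n"]], (-5 + 0.5) / 2)
  expect_equal(mid[["dmax1"]], sqrt(5 * 1000))
})

test_that("Latin hypercube samples are stratified on the sampling scale", {
  sp <- sa_parameter_space("dox_cyc")
  n_s <- 64
  X <- lhs_sample(sp, n_s, seed = 4)
  expect_equal(dim(X), c(n_s, 15))
  U <- nacdyn:::map_space_to_unit(X, sp)
  for (j in 1:15) {
    expect_true(all(X[, j] >= sp$lower[j] & X[, j] <= sp$upper[j]))
    # exactly one point per stratum
    strata <- floor(sort(U[, j]) * n_s)
    expect_equal(strata, 0:(n_s - 1))
  }
  # determinism
  expect_identical(X, lhs_sample(sp, n_s, seed = 4))
  expect_false(identical(X, lhs_sample(sp, n_s, seed = 5)))
  expect_error(lhs_sample(sp, 1), "at least 2")
})

test_that("log-scaled columns are uniform in log10", {
  sp <- sa_parameter_space("dox_cyc")
  X <- lhs_sample(sp, 10000, seed = 8)
  ks <- stats::ks.test(log10(X[, "D0"]), "punif", -6, -1)
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(X[, "E1n"], "punif", -5, 0.5)
  expect_gt(ks2$p.value, 0.01)
})

test_that("the column-swap design has the Saltelli structure", {
  A <- matrix(1:20, 4, 5)
  B <- matrix(101:120, 4, 5)
  d <- saltelli_design(A, B)
  expect_length(d$AB, 5)
  for (i in 1:5) {
    expect_equal(d$AB[[i]][, i], B[, i])
    expect_equal(d$AB[[i]][, -i], A[, -i])
  }
  # n_s (n_p + 2) total evaluations
  expect_equal(4 * (5 + 2), nrow(A) + nrow(B) + 5 * nrow(A))
  expect_equal(1000 * (15 + 2), 17000)
  expect_error(saltelli_design(A, B[, 1:3]), "identical shapes")
})

test_that("the total-effects estimator matches an independent transcription", {
  withr::with_seed(10, {
    YA <- rnorm(50)
    YB <- rnorm(50)
    YAB <- YA + 0.3 * rnorm(50)
  })
  # independent arithmetic of the same estimator
  yall <- c(YA, YB)
  vpop <- sum((yall - sum(yall) / 100)^2) / 100
  ref <- sum((YA - YAB)^2) / (2 * 50 * vpop)
  expect_equal(total_effects(YA, YB, YAB), ref, tolerance = 1e-12)
  expect_equal(total_effects(YA, YB, YA), 0)
  expect_error(total_effects(rep(1, 5), rep(1, 5), rep(1, 5)), "variance")
})

test_that("the estimator is invariant to affine rescaling of the output", {
  withr::with_seed(11, {
    YA <- rnorm(200); YB <- rnorm(200); YAB <- YA + 0.5 * rnorm(200)
  })
  s0 <- total_effects(YA, YB, YAB)
  s1 <- total_effects(7 * YA - 3, 7 * YB - 3, 7 * YAB - 3)
  expect_equal(s1, s0, tolerance = 1e-12)
})

test_that("total effects recover the closed-form indices of a linear model", {
  a <- c(4, 2, 1)
  space <- tibble::tibble(name = c("x1", "x2", "x3"), lower = 0, upper = 1,
                          scale = "regular", units = "")
  n_s <- 4096
  unit <- withr::with_seed(12, lhs::randomLHS(2 * n_s, 3))
  A <- unit[1:n_s, ]
  B <- unit[n_s + (1:n_s), ]
  d <- saltelli_design(A, B)
  f <- function(M) as.vector(M %*% a)
  YA <- f(A); YB <- f(B)
  truth <- a^2 / sum(a^2)
  for (i in 1:3) {
    st <- total_effects(YA, YB, f(d$AB[[i]]))
    expect_lt(abs(st - truth[i]), 0.05)
  }
})

test_that("total effects recover the analytic Ishigami indices", {
  a <- 7; b <- 0.1
  f <- function(M) sin(M[, 1]) + a * sin(M[, 2])^2 + b * M[, 3]^4 * sin(M[, 1])
  n_s <- 8192
  unit <- withr::with_seed(13, lhs::randomLHS(2 * n_s, 3))
  M <- 2 * pi * unit - pi
  A <- M[1:n_s, ]; B <- M[n_s + (1:n_s), ]
  d <- saltelli_design(A, B)
  YA <- f(A); YB <- f(B)
  # analytic total indices of the Ishigami function
  vy <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  st_true <- c(
    (1 / 2 * (1 + b * pi^4 / 5)^2 + 8 * b^2 * pi^8 / 225) / vy,
    (a^2 / 8) / vy,
    (8 * b^2 * pi^8 / 225) / vy
  )
  for (i in 1:3) {
    st <- total_effects(YA, YB, f(d$AB[[i]]))
    expect_lt(abs(st - st_true[i]), 0.05)
  }
})

test_that("bootstrap intervals behave for degenerate and generic inputs", {
  withr::with_seed(14, {
    YA <- rnorm(100); YB <- rnorm(100); YAB <- YA + 0.4 * rnorm(100)
  })
  expect_equal(bootstrap_ci(YA, YB, YA, seed = 1), c(lo = 0, hi = 0))
  ci <- bootstrap_ci(YA, YB, YAB, seed = 2)
  expect_identical(ci, bootstrap_ci(YA, YB, YAB, seed = 2))
  expect_lt(ci[1], ci[2])
  # percentile intervals almost always cover the point estimate
  cover <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    withr::with_seed(500 + r, {
      A <- matrix(runif(3 * 128), ncol = 3)
      Bm <- matrix(runif(3 * 128), ncol = 3)
    })
    f <- function(M) 3 * M[, 1] + M[, 2] + 0.5 * M[, 3]
    ABi <- A; ABi[, 1] <- Bm[, 1]
    st <- total_effects(f(A), f(Bm), f(ABi))
    ci_r <- bootstrap_ci(f(A), f(Bm), f(ABi), n_boot = 300, seed = r)
    if (st >= ci_r[1] && st <= ci_r[2]) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.9)
})

test_that("a campaign with one free parameter attributes all variance to it", {
  sc <- tiny_scenario()
  sp <- sa_parameter_space("dox_cyc")
  mid <- space_midpoints(sp)
  sp$lower <- mid
  sp$upper <- mid
  free <- sp$name == "rho0"
  sp$lower[free] <- 1e-3
  sp$upper[free] <- 1e-1
  sa <- run_sa(sc, "dox_cyc", n_s = 8, seed = 21, n_boot = 50, space = sp)
  n_t <- length(sa$times)
  st_end <- sa$ST[n_t, "NT", ]
  expect_gt(st_end[["rho0"]], 0.9)
  expect_true(all(st_end[sp$name != "rho0"] == 0))
  expect_equal(influential_parameters(sa), "rho0")
})

test_that("campaigns are reproducible and checkpoint-resumable", {
  sc <- tiny_scenario()
  ck <- withr::local_tempdir()
  sa1 <- run_sa(sc, "dox_cyc", n_s = 6, seed = 33, n_boot = 50,
                checkpoint_dir = ck)
  # resume from existing checkpoints reproduces bitwise
  sa2 <- run_sa(sc, "dox_cyc", n_s = 6, seed = 33, n_boot = 50,
                checkpoint_dir = ck)
  expect_identical(sa1$ST, sa2$ST)
  expect_identical(sa1$ci, sa2$ci)
  # a fresh uncheckpointed run agrees too
  sa3 <- run_sa(sc, "dox_cyc", n_s = 6, seed = 33, n_boot = 50)
  expect_identical(sa1$ST, sa3$ST)
  # partial checkpoints (one chunk removed) still reproduce
  files <- list.files(ck, full.names = TRUE)
  file.remove(files[1])
  sa4 <- run_sa(sc, "dox_cyc", n_s = 6, seed = 33, n_boot = 50,
                checkpoint_dir = ck)
  expect_identical(sa1$ST, sa4$ST)
})

test_that("reduced-model comparison is exact when nothing is frozen", {
  sc <- tiny_scenario()
  sa <- run_sa(sc, "dox_cyc", n_s = 6, seed = 44, n_boot = 50,
               keep_final_density = TRUE)
  cmp <- reduced_model_comparison(sc, sa, influential = PARAM_NAMES,
                                  rows = 1:6, compute_mrd = TRUE)
  g <- glance(cmp)
  expect_equal(cmp$VT_orig, cmp$VT_red)
  expect_equal(cmp$NT_orig, cmp$NT_red, tolerance = 1e-12)
  expect_equal(cmp$MRD_orig, cmp$MRD_red, tolerance = 1e-12)
  expect_true(all(g$pcc == 1))
  expect_error(reduced_model_comparison(sc, sa, influential = character(0)),
               "empty")
})
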