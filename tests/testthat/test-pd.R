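test_that("combined maximal effect follows the efficacy-synergy rule", {
  expect_equal(e3(-1, 0.4, 0), -1)
  expect_equal(e3(1, 1, 0.7), 1)
  expect_equal(e3(-5, 0.5, 0.3), -6.8)
  expect_equal(e3(0.2, -0.3, -0.1), 0.9 * (-0.3) + 0.1)
})

test_that("the rate surface reduces correctly with zero or one drug", {
  p <- pd_params(rho0 = 0.025, h1 = 2, h2 = 1.5, C1 = 0.01, C2 = 10,
                 E1n = -2, E2n = 0.3, a1 = 5, a2 = 0.5, beta = 0.1)
  expect_equal(musyc_rho(0, 0, p), 0.025)
  # single-drug Hill with half-effect at normalized concentration 1
  expect_equal(musyc_rho(1, 0, p), 0.025 * (1 + p$E1n) / 2)
  expect_equal(musyc_rho(0, 1, p), 0.025 * (1 + p$E2n) / 2)
  # saturating limits
  expect_equal(musyc_rho(1e12, 0, p), 0.025 * p$E1n, tolerance = 1e-6)
  expect_equal(musyc_rho(0, 1e12, p), 0.025 * p$E2n, tolerance = 1e-6)
  expect_error(musyc_rho(-1, 0, p), "non-negative")
})

test_that("the rate surface matches an extended-precision transcription", {
  # frozen oracle: each row evaluated with a 60-digit verbatim
  # transcription of the four weight polynomials and the combined effect
  oracle <- read.csv(text = "
h1,h2,C1,C2,E1n,E2n,a1,a2,beta,d1,d2,ratio
25,3.2,0.016,1600,-5,0.5,1300,40,0.3,0,0,1
25,3.2,0.016,1600,-5,0.5,1300,40,0.3,1,0,-2
25,3.2,0.016,1600,-5,0.5,1300,40,0.3,0.5,2,-6.79999999997875
25,3.2,0.016,1600,-5,0.5,1300,40,0.3,100,30,-6.7999999999999963
25,3.2,0.016,1600,-5,0.5,1300,40,0.3,1000,1000,-6.7999999999999999
2,0.4,0.00063,0.13,-2,-0.5,1e-4,1e-4,-0.2,0,0,1
2,0.4,0.00063,0.13,-2,-0.5,1e-4,1e-4,-0.2,1,0,-0.5
2,0.4,0.00063,0.13,-2,-0.5,1e-4,1e-4,-0.2,0.5,2,-0.060300178489125802
2,0.4,0.00063,0.13,-2,-0.5,1e-4,1e-4,-0.2,100,30,-1.9456323233590414
2,0.4,0.00063,0.13,-2,-0.5,1e-4,1e-4,-0.2,1000,1000,-1.8291275262193076
6.3,0.3,0.001,40,-3,0.5,1e4,2.5,0.2,0,0,1
6.3,0.3,0.001,40,-3,0.5,1e4,2.5,0.2,1,0,-1
6.3,0.3,0.001,40,-3,0.5,1e4,2.5,0.2,0.5,2,-2.3836687769400984
6.3,0.3,0.001,40,-3,0.5,1e4,2.5,0.2,100,30,-3.7822095578478148
6.3,0.3,0.001,40,-3,0.5,1e4,2.5,0.2,1000,1000,-3.7936954529197358
1.7,1.1,0.004,0.063,0.2,-1.3,5,0.7,0.1,0,0,1
1.7,1.1,0.004,0.063,0.2,-1.3,5,0.7,0.1,1,0,0.60000000000000001
1.7,1.1,0.004,0.063,0.2,-1.3,5,0.7,0.1,0.5,2,-0.71455992268120329
1.7,1.1,0.004,0.063,0.2,-1.3,5,0.7,0.1,100,30,-1.5228449285439464
1.7,1.1,0.004,0.063,0.2,-1.3,5,0.7,0.1,1000,1000,-1.5298490189654221
")
  for (r in seq_len(nrow(oracle))) {
    o <- oracle[r, ]
    p <- pd_params(rho0 = 1, h1 = o$h1, h2 = o$h2, C1 = o$C1, C2 = o$C2,
                   E1n = o$E1n, E2n = o$E2n, a1 = o$a1, a2 = o$a2,
                   beta = o$beta)
    expect_equal(musyc_rho(o$d1, o$d2, p), o$ratio, tolerance = 1e-10,
                 info = paste("oracle row", r))
  }
})

test_that("detailed balance collapses the surface to the reduced form", {
  # a2^h1 == a1^h2 enforced by construction
  base <- list(rho0 = 0.03, h1 = 2.3, h2 = 1.4, C1 = 0.02, C2 = 7,
               E1n = -3, E2n = 0.4, beta = 0.15)
  for (a1 in c(0.01, 1, 40)) {
    p <- do.call(pd_params, c(base, list(a1 = a1, a2 = a1^(base$h2 / base$h1))))
    d <- expand.grid(d1 = c(0, 0.1, 1, 10, 300), d2 = c(0, 0.05, 2, 80))
    full <- musyc_rho(d$d1, d$d2, p)
    red <- musyc_rho_db(d$d1, d$d2, p)
    expect_lt(max(abs(full - red) / pmax(abs(full), 1e-12)), 1e-10)
  }
  # without detailed balance the forms genuinely differ
  p2 <- do.call(pd_params, c(base, list(a1 = 10, a2 = 0.01)))
  expect_gt(max(abs(musyc_rho(2, 3, p2) - musyc_rho_db(2, 3, p2))), 1e-6)
})

test_that("the surface is symmetric under swapping the drug labels", {
  draws <- withr::with_seed(31, replicate(20, list(
    h1 = runif(1, 0.4, 5), h2 = runif(1, 0.4, 5),
    C1 = 10^runif(1, -3, 2), C2 = 10^runif(1, -3, 2),
    E1n = runif(1, -5, 0.5), E2n = runif(1, -5, 0.5),
    a1 = 10^runif(1, -3, 2), a2 = 10^runif(1, -3, 2),
    beta = runif(1, -0.2, 0.3)
  ), simplify = FALSE))
  for (s in draws) {
    p12 <- do.call(pd_params, c(list(rho0 = 0.025), s))
    p21 <- pd_params(rho0 = 0.025, h1 = s$h2, h2 = s$h1, C1 = s$C2,
                     C2 = s$C1, E1n = s$E2n, E2n = s$E1n, a1 = s$a2,
                     a2 = s$a1, beta = s$beta)
    d1 <- withr::with_seed(32, runif(5, 0, 50))
    d2 <- withr::with_seed(33, runif(5, 0, 50))
    expect_equal(musyc_rho(d1, d2, p12), musyc_rho(d2, d1, p21),
                 tolerance = 1e-12)
  }
})

test_that("response is bounded by rho0 and monotone for inhibitory drugs", {
  draws <- withr::with_seed(41, replicate(25, list(
    h1 = runif(1, 0.4, 6), h2 = runif(1, 0.4, 6),
    C1 = 10^runif(1, -3, 2), C2 = 10^runif(1, -2, 3),
    E1n = runif(1, -5, 1), E2n = runif(1, -5, 1),
    a1 = 10^runif(1, -3, 2), a2 = 10^runif(1, -3, 2),
    beta = runif(1, -0.5, 0.3)
  ), simplify = FALSE))
  d <- 10^seq(-3, 3, length.out = 40)
  for (s in draws) {
    p <- do.call(pd_params, c(list(rho0 = 0.025), s))
    grid <- expand.grid(d1 = c(0, d[c(5, 20, 35)]), d2 = c(0, d[c(8, 30)]))
    expect_true(all(musyc_rho(grid$d1, grid$d2, p) <= 0.025 + 1e-12))
    if (s$E1n < 1) {
      single <- musyc_rho(d, 0 * d, p)
      expect_true(all(diff(single) <= 1e-12))
    }
  }
})

test_that("normalization divides by the baseline rate and the EC50", {
  out <- normalize_pd(E = -0.05, rho0 = 0.025, d = 3, C = 1.5)
  expect_equal(out$E_norm, -2)
  expect_equal(out$d_norm, 2)
  expect_equal(normalize_pd(0.025, 0.025, 1.5, 1.5)$E_norm, 1)
  expect_error(normalize_pd(1, 0, 1, 1), "positive")
})

test_that("response-curve export covers both drugs and the combination", {
  p <- pd_params(rho0 = 0.025, h1 = 2, h2 = 1, C1 = 0.01, C2 = 1,
                 E1n = -1, E2n = 0, a1 = 1, a2 = 1, beta = 0)
  tab <- pd_response_curves(p, d_max = 5, n = 11)
  expect_s3_class(tab, "tbl_df")
  expect_setequal(unique(tab$curve), c("drug1", "drug2", "combination"))
  expect_equal(tab$rho[tab$curve == "drug1" & tab$d1n == 0], 0.025)
})
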