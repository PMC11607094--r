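#' MuSyC pharmacodynamic parameters
#'
#' Parameters of the normalized two-drug MuSyC dose-response surface for the
#' tumor cell net proliferation rate: the drug-free baseline rate `rho0`
#' (1/day), Hill coefficients `h1`, `h2`, half-maximal effective
#' concentrations `C1`, `C2` (uM), normalized maximal effects `E1n`, `E2n`
#' (maximal drug-induced proliferation rate divided by `rho0`; negative
#' values mean net cell kill), synergies of potency `a1`, `a2`, and the
#' synergy of efficacy `beta`. The combined maximal effect `E3n` follows
#' from `E1n`, `E2n` and `beta` via [e3()].
#'
#' @param rho0 Baseline net proliferation rate (1/day, positive).
#' @param h1,h2 Hill coefficients (positive).
#' @param C1,C2 Half-maximal effective concentrations (uM, positive).
#' @param E1n,E2n Normalized maximal effects (may be negative).
#' @param a1,a2 Synergies of potency (positive).
#' @param beta Synergy of efficacy.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(rho0, h1, h2, C1, C2, E1n, E2n, a1, a2, beta) {
  vals <- c(rho0 = rho0, h1 = h1, h2 = h2, C1 = C1, C2 = C2,
            E1n = E1n, E2n = E2n, a1 = a1, a2 = a2, beta = beta)
  if (any(!is.finite(vals))) stop("pd parameters must be finite", call. = FALSE)
  if (rho0 <= 0) stop("rho0 must be positive", call. = FALSE)
  if (h1 <= 0 || h2 <= 0) stop("Hill coefficients must be positive", call. = FALSE)
  if (C1 <= 0 || C2 <= 0) stop("EC50 values must be positive", call. = FALSE)
  if (a1 <= 0 || a2 <= 0) stop("synergies of potency must be positive", call. = FALSE)
  structure(as.list(vals), class = "pd_params")
}

#' Combined maximal effect of a drug pair
#'
#' The normalized maximal effect when both drugs are at saturating
#' concentration: `(1 + beta) * min(E1n, E2n) - beta`. A positive synergy of
#' efficacy `beta` pushes the combined effect beyond the stronger single
#' drug; the value is deliberately not clamped to the single-drug range.
#'
#' @param E1n,E2n Normalized maximal effects of the two drugs.
#' @param beta Synergy of efficacy.
#' @return The combined normalized maximal effect.
#' @examples
#' e3(-5, 0.5, 0.3) # 1.3 * (-5) - 0.3 = -6.8
#' @export
e3 <- function(E1n, E2n, beta) {
  (1 + beta) * pmin(E1n, E2n) - beta
}

# power with the continuous extension 0^h = 0 for h > 0 (avoids 0^0 = 1
# surprises when h < 1 meets a zero concentration)
pow0 <- function(x, h) {
  out <- x^h
  out[x == 0] <- 0
  out
}

#' Drug-modulated net proliferation rate (MuSyC surface)
#'
#' Evaluates the normalized two-drug MuSyC net proliferation rate
#' voxelwise: a rational function of the normalized concentrations whose
#' four weighting polynomials carry the Hill exponents, EC50 magnitudes and
#' both synergy-of-potency coefficients. With no drug the rate reduces to
#' `rho0`; with a single drug it reduces to a Hill curve from `rho0` to
#' `rho0 * E1n` with half-effect at normalized concentration 1.
#'
#' For numerical conditioning the four weights are evaluated relative to the
#' drug-free weight (the surface is scale-invariant in the weights), which
#' keeps intermediate magnitudes moderate even for large EC50^Hill terms.
#'
#' @param d1n,d2n Normalized concentrations: scalars, arrays, or
#'   [scalar_field()] objects (non-negative).
#' @param params A [pd_params()] object.
#' @return The net proliferation rate (1/day), same shape as the inputs.
#' @export
musyc_rho <- function(d1n, d2n, params) {
  stopifnot(inherits(params, "pd_params"))
  as_field <- inherits(d1n, "scalar_field") || inherits(d2n, "scalar_field")
  grid <- NULL
  if (inherits(d1n, "scalar_field")) { grid <- d1n$grid; d1n <- d1n$values }
  if (inherits(d2n, "scalar_field")) { grid <- d2n$grid; d2n <- d2n$values }
  if (any(d1n < 0) || any(d2n < 0)) {
    stop("normalized concentrations must be non-negative", call. = FALSE)
  }
  p <- params
  T1 <- pow0(d1n, p$h1)
  T2 <- pow0(d2n, p$h2)
  c1h <- p$C1^p$h1
  c2h <- p$C2^p$h2
  k0 <- c1h + c2h
  # weights divided by the constant part k0 of the drug-free weight
  s1 <- pow0(p$C1 * p$a2 * d1n, p$h1) / k0
  s2 <- pow0(p$C2 * p$a1 * d2n, p$h2) / k0
  w1 <- p$a1^p$h2 * pow0(p$C1 * d1n, p$h1) / k0
  w2 <- p$a2^p$h1 * pow0(p$C2 * d2n, p$h2) / k0
  g0 <- 1 + s1 + s2
  g1 <- 1 + s1 + w2
  g2 <- 1 + w1 + s2
  g3 <- ((p$C1 * p$a2)^p$h1 + (p$C2 * p$a1)^p$h2) / k0 +
    p$a1^p$h2 * s1 + p$a2^p$h1 * s2
  E3n <- e3(p$E1n, p$E2n, p$beta)
  num <- g0 + g1 * T1 * p$E1n + g2 * T2 * p$E2n + g3 * T1 * T2 * E3n
  den <- g0 + g1 * T1 + g2 * T2 + g3 * T1 * T2
  rho <- p$rho0 * num / den
  if (as_field) scalar_field(grid, array(rho, dim = grid$shape)) else rho
}

#' Detailed-balance reduction of the MuSyC surface
#'
#' When the two synergies of potency satisfy the detailed-balance relation
#' `a2^h1 == a1^h2`, the four MuSyC weights collapse and the rate takes the
#' compact form
#' `rho0 * (1 + T1*E1n + T2*E2n + a1^h2*T1*T2*E3n) / (1 + T1 + T2 + a1^h2*T1*T2)`
#' with `T1 = d1n^h1`, `T2 = d2n^h2`. This function evaluates that reduced
#' form directly; it agrees with [musyc_rho()] exactly when detailed balance
#' holds.
#'
#' @inheritParams musyc_rho
#' @return The net proliferation rate (1/day).
#' @export
musyc_rho_db <- function(d1n, d2n, params) {
  stopifnot(inherits(params, "pd_params"))
  as_field <- inherits(d1n, "scalar_field") || inherits(d2n, "scalar_field")
  grid <- NULL
  if (inherits(d1n, "scalar_field")) { grid <- d1n$grid; d1n <- d1n$values }
  if (inherits(d2n, "scalar_field")) { grid <- d2n$grid; d2n <- d2n$values }
  if (any(d1n < 0) || any(d2n < 0)) {
    stop("normalized concentrations must be non-negative", call. = FALSE)
  }
  p <- params
  T1 <- pow0(d1n, p$h1)
  T2 <- pow0(d2n, p$h2)
  a <- p$a1^p$h2
  E3n <- e3(p$E1n, p$E2n, p$beta)
  rho <- p$rho0 * (1 + T1 * p$E1n + T2 * p$E2n + a * T1 * T2 * E3n) /
    (1 + T1 + T2 + a * T1 * T2)
  if (as_field) scalar_field(grid, array(rho, dim = grid$shape)) else rho
}

#' Normalize a drug effect and concentration
#'
#' Converts an absolute maximal drug effect (1/day) and concentration (uM)
#' to their normalized counterparts: effect divided by the baseline
#' proliferation rate and concentration divided by the drug's half-maximal
#' effective concentration.
#'
#' @param E Maximal drug effect (1/day).
#' @param rho0 Baseline proliferation rate (1/day, positive).
#' @param d Concentration (uM).
#' @param C Half-maximal effective concentration (uM, positive).
#' @return A list with `E_norm` and `d_norm`.
#' @export
normalize_pd <- function(E, rho0, d, C) {
  if (rho0 <= 0 || C <= 0) {
    stop("rho0 and C must be positive", call. = FALSE)
  }
  list(E_norm = E / rho0, d_norm = d / C)
}

#' Single-drug and combination response curves as a tibble
#'
#' Evaluates the proliferation-rate surface along concentration sweeps for
#' each drug alone and for the fixed-ratio combination, convenient for
#' exporting response curves.
#'
#' @param params A [pd_params()] object.
#' @param d_max Upper end of the normalized concentration sweep.
#' @param n Number of points per sweep.
#' @return A tibble with columns `curve`, `d1n`, `d2n`, `rho`.
#' @export
pd_response_curves <- function(params, d_max = 10, n = 101) {
  d <- seq(0, d_max, length.out = n)
  dplyr::bind_rows(
    tibble::tibble(curve = "drug1", d1n = d, d2n = 0,
                   rho = musyc_rho(d, 0 * d, params)),
    tibble::tibble(curve = "drug2", d1n = 0, d2n = d,
                   rho = musyc_rho(0 * d, d, params)),
    tibble::tibble(curve = "combination", d1n = d, d2n = d,
                   rho = musyc_rho(d, d, params))
  )
}

# ---------------------------------------------------------------------------
# Separable fast path used by the batched solver.
#
# With bolus pharmacokinetics the normalized concentration factorizes as
# d_i(x, t) = A_i(t) * p(x), so d_i^h_i = A_i(t)^h_i * p(x)^h_i and the whole
# MuSyC rational surface becomes a ratio of two polynomials in the two static
# basis fields P1 = p^h1, P2 = p^h2 with time-dependent scalar coefficients
# on the monomials {1, P1, P2, P1^2, P2^2, P1*P2, P1^2*P2, P1*P2^2}.
# Coefficients are assembled in log space and rescaled by their common
# maximum so extreme EC50^Hill magnitudes cannot overflow.
#
# Returns an 16 x n_t matrix: rows 1..8 numerator coefficients (including the
# rho0 factor), rows 9..16 denominator coefficients, one column per time.
musyc_basis_coefs <- function(params, A1, A2) {
  p <- params
  n_t <- length(A1)
  stopifnot(length(A2) == n_t)
  lg <- function(x) ifelse(x > 0, log(x), -Inf)
  lC1 <- log(p$C1); lC2 <- log(p$C2)
  la1 <- log(p$a1); la2 <- log(p$a2)
  lA1 <- lg(A1); lA2 <- lg(A2)
  # log magnitudes of the multiplicative building blocks (vectors over time)
  l_u1 <- p$h1 * lA1                       # A1^h1
  l_u2 <- p$h2 * lA2
  l_s1 <- p$h1 * (lC1 + la2 + lA1)         # (C1 a2 A1)^h1
  l_s2 <- p$h2 * (lC2 + la1 + lA2)
  l_w1 <- p$h2 * la1 + p$h1 * (lC1 + lA1)  # a1^h2 (C1 A1)^h1
  l_w2 <- p$h1 * la2 + p$h2 * (lC2 + lA2)
  l_k1 <- p$h1 * lC1                       # C1^h1 (constant)
  l_k2 <- p$h2 * lC2
  l_q1 <- p$h1 * (lC1 + la2)               # (C1 a2)^h1
  l_q2 <- p$h2 * (lC2 + la1)
  l_a1h2 <- p$h2 * la1
  l_a2h1 <- p$h1 * la2
  e3n <- e3(p$E1n, p$E2n, p$beta)

  # denominator monomial coefficients as sums of signed exponential terms;
  # list of (log magnitude matrix-rows, multiplier)
  terms <- list(
    # row, log-magnitude (length n_t), numerator factor, denominator factor
    list(1, rep(l_k1, n_t), 1, 1),
    list(1, rep(l_k2, n_t), 1, 1),
    list(2, l_s1, 1, 1),
    list(2, l_u1 + l_k1, p$E1n, 1),
    list(2, l_u1 + l_k2, p$E1n, 1),
    list(3, l_s2, 1, 1),
    list(3, l_u2 + l_k1, p$E2n, 1),
    list(3, l_u2 + l_k2, p$E2n, 1),
    list(4, l_u1 + l_s1, p$E1n, 1),
    list(5, l_u2 + l_s2, p$E2n, 1),
    list(6, l_u1 + l_w2, p$E1n, 1),
    list(6, l_u2 + l_w1, p$E2n, 1),
    list(6, l_u1 + l_u2 + l_q1, e3n, 1),
    list(6, l_u1 + l_u2 + l_q2, e3n, 1),
    list(7, l_u1 + l_u2 + l_a1h2 + l_s1, e3n, 1),
    list(8, l_u1 + l_u2 + l_a2h1 + l_s2, e3n, 1)
  )
  all_logs <- do.call(rbind, lapply(terms, `[[`, 2))
  lmax <- apply(all_logs, 2, max)
  lmax[!is.finite(lmax)] <- 0
  num <- matrix(0, 8, n_t)
  den <- matrix(0, 8, n_t)
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    mag <- exp(all_logs[k, ] - lmax)
    num[tm[[1]], ] <- num[tm[[1]], ] + tm[[3]] * mag
    den[tm[[1]], ] <- den[tm[[1]], ] + tm[[4]] * mag
  }
  rbind(p$rho0 * num, den)
}
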