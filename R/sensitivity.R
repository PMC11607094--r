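#' Sensitivity-analysis parameter space
#'
#' The admissible ranges of the 15 model parameters examined by the global
#' sensitivity analysis, per regimen. Most parameters are sampled uniformly
#' on a base-10 logarithmic scale; the normalized maximal effects, the
#' synergy of efficacy and the drug decay rates are sampled uniformly on
#' their natural (regular) scale because they can take values of either
#' sign or span less than an order of magnitude.
#'
#' @param kind `"dox_cyc"` (doxorubicin + cyclophosphamide) or `"ptx_cpt"`
#'   (paclitaxel + carboplatin).
#' @return A tibble of class `param_space` with columns `name`, `lower`,
#'   `upper`, `scale` (`"log"` or `"regular"`), `units`, in the canonical
#'   parameter order of [PARAM_NAMES].
#' @export
sa_parameter_space <- function(kind = c("dox_cyc", "ptx_cpt")) {
  kind <- match.arg(kind)
  base <- tibble::tribble(
    ~name,     ~scale,    ~units,
    "D0",      "log",     "mm^2/day",
    "rho0",    "log",     "1/day",
    "h1",      "log",     "",
    "h2",      "log",     "",
    "C1",      "log",     "uM",
    "C2",      "log",     "uM",
    "E1n",     "regular", "",
    "E2n",     "regular", "",
    "a1",      "log",     "",
    "a2",      "log",     "",
    "beta",    "regular", "",
    "dmax1",   "log",     "",
    "dmax2",   "log",     "",
    "gamma1",  "regular", "1/day",
    "gamma2",  "regular", "1/day"
  )
  ranges <- if (kind == "dox_cyc") {
    list(D0 = c(1.0e-6, 1.0e-1), rho0 = c(1.0e-3, 1.0e-1),
         h1 = c(1.0, 25), h2 = c(0.4, 3.2),
         C1 = c(6.3e-4, 1.6e-2), C2 = c(1.3e-1, 1.6e3),
         E1n = c(-5, 0.5), E2n = c(-5, 0.5),
         a1 = c(1.0e-4, 1.3e3), a2 = c(1.0e-4, 40),
         beta = c(-0.2, 0.3),
         dmax1 = c(5.0, 1.0e3), dmax2 = c(5.0, 1.0e3),
         gamma1 = c(0.3, 0.6), gamma2 = c(1.7, 5.4))
  } else {
    list(D0 = c(1.0e-6, 1.0e-1), rho0 = c(1.0e-3, 1.0e-1),
         h1 = c(1.0, 6.3), h2 = c(0.3, 3.2),
         C1 = c(1.0e-3, 4.0e-3), C2 = c(6.3e-2, 40),
         E1n = c(-3, 0.5), E2n = c(-3, 0.5),
         a1 = c(1.0e-4, 1.0e4), a2 = c(1.0e-4, 2.5),
         beta = c(-0.1, 0.2),
         dmax1 = c(5.0, 1.0e3), dmax2 = c(5.0, 1.0e3),
         gamma1 = c(0.3, 1.1), gamma2 = c(0.1, 0.2))
  }
  out <- base
  out$lower <- unname(vapply(out$name, function(nm) ranges[[nm]][1], numeric(1)))
  out$upper <- unname(vapply(out$name, function(nm) ranges[[nm]][2], numeric(1)))
  out <- out[, c("name", "lower", "upper", "scale", "units")]
  attr(out, "regimen") <- kind
  class(out) <- c("param_space", class(out))
  out
}

validate_space <- function(space) {
  stopifnot(inherits(space, "data.frame"),
            all(c("name", "lower", "upper", "scale") %in% names(space)))
  if (any(space$lower > space$upper)) {
    stop("parameter lower bounds must not exceed upper bounds", call. = FALSE)
  }
  if (any(space$scale == "log" & space$lower <= 0)) {
    stop("log-scaled parameters need positive lower bounds", call. = FALSE)
  }
  if (!all(space$scale %in% c("log", "regular"))) {
    stop("sampling scale must be 'log' or 'regular'", call. = FALSE)
  }
  invisible(space)
}

#' Midpoints of a parameter space
#'
#' The arithmetic midpoint of regular-scaled ranges and the geometric
#' midpoint of log-scaled ranges, used to fix non-influential parameters in
#' the reduced model.
#'
#' @param space A [sa_parameter_space()] tibble.
#' @return Named numeric vector of midpoints.
#' @export
space_midpoints <- function(space) {
  validate_space(space)
  mid <- (space$lower + space$upper) / 2
  lg <- space$scale == "log"
  mid[lg] <- 10^((log10(space$lower[lg]) + log10(space$upper[lg])) / 2)
  stats::setNames(mid, space$name)
}

#' Latin hypercube sample of a parameter space
#'
#' Draws a stratified sample: each parameter's unit interval is divided
#' into `n_s` equal strata holding exactly one point, then mapped to the
#' parameter's range on its sampling scale (base-10 logarithmic or
#' regular). Deterministic for a given seed.
#'
#' @param space A [sa_parameter_space()] tibble.
#' @param n_s Number of samples (rows), at least 2.
#' @param seed Integer seed.
#' @return An `n_s x n_p` matrix with parameters as named columns.
#' @export
lhs_sample <- function(space, n_s, seed = 1L) {
  validate_space(space)
  if (n_s < 2) stop("n_s must be at least 2", call. = FALSE)
  unit <- withr::with_seed(seed, lhs::randomLHS(n_s, nrow(space)))
  map_unit_to_space(unit, space)
}

# map an n x n_p matrix of unit-cube coordinates to parameter values
map_unit_to_space <- function(unit, space) {
  out <- matrix(0, nrow(unit), nrow(space),
                dimnames = list(NULL, space$name))
  for (j in seq_len(nrow(space))) {
    if (space$scale[j] == "log") {
      lo <- log10(space$lower[j]); hi <- log10(space$upper[j])
      out[, j] <- 10^(lo + unit[, j] * (hi - lo))
    } else {
      out[, j] <- space$lower[j] + unit[, j] * (space$upper[j] - space$lower[j])
    }
  }
  out
}

# inverse of map_unit_to_space (used by the stratification tests)
map_space_to_unit <- function(values, space) {
  out <- matrix(0, nrow(values), nrow(space),
                dimnames = list(NULL, space$name))
  for (j in seq_len(nrow(space))) {
    if (space$lower[j] == space$upper[j]) next
    if (space$scale[j] == "log") {
      lo <- log10(space$lower[j]); hi <- log10(space$upper[j])
      out[, j] <- (log10(values[, j]) - lo) / (hi - lo)
    } else {
      out[, j] <- (values[, j] - space$lower[j]) /
        (space$upper[j] - space$lower[j])
    }
  }
  out
}

#' Saltelli column-swap design from two base samples
#'
#' Builds the `n_p` matrices `AB[[i]]` that equal `A` except that column
#' `i` is taken from `B`. Together with `A` and `B` the design requires
#' `n_s * (n_p + 2)` model evaluations.
#'
#' @param A,B Two equally shaped sample matrices.
#' @return A list with `A`, `B`, `AB` (list of `n_p` matrices) of class
#'   `saltelli_design`.
#' @export
saltelli_design <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    stop("A and B must have identical shapes", call. = FALSE)
  }
  AB <- lapply(seq_len(ncol(A)), function(i) {
    M <- A
    M[, i] <- B[, i]
    M
  })
  structure(list(A = A, B = B, AB = AB), class = "saltelli_design")
}

#' Total-effects sensitivity index (Jansen estimator)
#'
#' Estimates the total-effects index of one parameter from the model
#' outputs on the base samples `YA`, `YB` and the column-swapped sample
#' `YAB_i`:
#' `S_T = sum_j (YA_j - YAB_j)^2 / (2 n_s Var(c(YA, YB)))`,
#' with the variance taken over all `2 n_s` base outputs (population
#' normalization). Non-negative by construction.
#'
#' @param YA,YB,YAB_i Numeric vectors of equal length `n_s`.
#' @return The estimated total-effects index.
#' @export
total_effects <- function(YA, YB, YAB_i) {
  n_s <- length(YA)
  if (length(YB) != n_s || length(YAB_i) != n_s) {
    stop("YA, YB and YAB_i must have equal length", call. = FALSE)
  }
  yall <- c(YA, YB)
  v <- mean((yall - mean(yall))^2)
  if (v <= 0) {
    stop("total variance of the base outputs is zero; indices undefined",
         call. = FALSE)
  }
  sum((YA - YAB_i)^2) / (2 * n_s * v)
}

#' Bootstrap confidence interval for a total-effects index
#'
#' Percentile interval from paired resampling: sample indices are drawn
#' with replacement jointly across `YA`, `YB` and `YAB_i`, the index is
#' re-estimated on each resample, and the interval is taken from the
#' percentiles of the bootstrap distribution.
#'
#' @inheritParams total_effects
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(YA, YB, YAB_i, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  n_s <- length(YA)
  stats_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_s, n_s, replace = TRUE)
      yall <- c(YA[idx], YB[idx])
      v <- mean((yall - mean(yall))^2)
      if (v <= 0) return(NA_real_)
      sum((YA[idx] - YAB_i[idx])^2) / (2 * n_s * v)
    }, numeric(1))
  })
  stats_boot <- stats_boot[is.finite(stats_boot)]
  if (!length(stats_boot)) return(c(lo = 0, hi = 0))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(stats_boot, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  c(lo = qs[1], hi = qs[2])
}

#' Global variance-based sensitivity analysis of the model
#'
#' Runs the full Saltelli campaign on a scenario: two Latin hypercube base
#' samples of the 15-parameter space, the column-swap design (a total of
#' `n_s * 17` model evaluations), time-resolved total-effects indices for
#' both tumor volume and total cell count, bootstrap confidence intervals
#' at the end of treatment, and influence labels (`S_T > eps_s`).
#'
#' The campaign is deterministic for a given seed, independent of the
#' execution order of the design rows, and can be checkpointed: pass a
#' `checkpoint_dir` and an interrupted campaign resumes from the completed
#' chunks with bitwise-identical results.
#'
#' @param scenario An `nac_scenario`.
#' @param regimen_kind `"dox_cyc"` or `"ptx_cpt"`, or an `nac_regimen`
#'   (whose `kind` selects the parameter ranges).
#' @param n_s Number of base samples.
#' @param seed Integer seed for sampling and bootstrap.
#' @param dt Time step (days).
#' @param mech_every Steps between mechanics solves.
#' @param eps_s Influence threshold on the total-effects index.
#' @param n_boot Bootstrap resamples for the end-of-treatment intervals.
#' @param qoi_stride Store the time-resolved indices every this many steps.
#' @param keep_final_density Keep the end-of-treatment density of the A and
#'   B rows (needed for reduced-model heterogeneity comparisons).
#' @param checkpoint_dir Optional directory for resumable chunk checkpoints.
#' @param space Optional override of the parameter space (same shape as
#'   [sa_parameter_space()]); ranges may be collapsed to points to freeze
#'   parameters.
#' @param chunk_size Runs per solver chunk.
#' @return An object of class `sa_result`; see [tidy.sa_result()].
#' @export
run_sa <- function(scenario, regimen_kind = "dox_cyc", n_s = 128,
                   seed = 1L, dt = 0.25, mech_every = 4L, eps_s = 0.1,
                   n_boot = 1000, qoi_stride = 4L,
                   keep_final_density = FALSE, checkpoint_dir = NULL,
                   space = NULL, chunk_size = 64L) {
  stopifnot(inherits(scenario, "nac_scenario"))
  regimen <- if (inherits(regimen_kind, "nac_regimen")) {
    regimen_kind
  } else {
    standard_regimen(regimen_kind)
  }
  if (is.null(space)) space <- sa_parameter_space(regimen$kind)
  validate_space(space)
  n_p <- nrow(space)
  if (eps_s <= 0 || eps_s >= 1) stop("eps_s must lie in (0, 1)", call. = FALSE)

  # two independent base samples from one seeded stream
  unit <- withr::with_seed(seed, lhs::randomLHS(2L * n_s, n_p))
  A <- map_unit_to_space(unit[seq_len(n_s), , drop = FALSE], space)
  B <- map_unit_to_space(unit[n_s + seq_len(n_s), , drop = FALSE], space)
  design <- saltelli_design(A, B)

  pmat <- t(rbind(design$A, design$B, do.call(rbind, design$AB)))
  rownames(pmat) <- space$name
  res <- simulate_batch(
    scenario, pmat, regimen, dt = dt, mech_every = mech_every,
    keep_final = keep_final_density, chunk_size = chunk_size,
    checkpoint_dir = checkpoint_dir, qoi_stride = qoi_stride
  )

  idxA <- seq_len(n_s)
  idxB <- n_s + seq_len(n_s)
  idxAB <- function(i) 2L * n_s + (i - 1L) * n_s + seq_len(n_s)

  n_t <- length(res$times)
  ST <- array(NA_real_, dim = c(n_t, 2, n_p),
              dimnames = list(NULL, c("VT", "NT"), space$name))
  collapsed <- space$lower == space$upper
  for (qi in 1:2) {
    Y <- if (qi == 1) res$VT else res$NT
    YA <- Y[, idxA, drop = FALSE]
    YB <- Y[, idxB, drop = FALSE]
    yall <- cbind(YA, YB)
    v <- rowMeans((yall - rowMeans(yall))^2)
    for (i in seq_len(n_p)) {
      YAB <- Y[, idxAB(i), drop = FALSE]
      num <- rowSums((YA - YAB)^2)
      ST[, qi, i] <- ifelse(v > 0, num / (2 * n_s * v), 0)
    }
  }

  ci <- array(NA_real_, dim = c(2, 2, n_p),
              dimnames = list(c("lo", "hi"), c("VT", "NT"), space$name))
  influential <- matrix(FALSE, 2, n_p,
                        dimnames = list(c("VT", "NT"), space$name))
  YA_T <- list(); YB_T <- list(); YAB_T <- list()
  for (qi in 1:2) {
    Y <- if (qi == 1) res$VT else res$NT
    yA <- Y[n_t, idxA]; yB <- Y[n_t, idxB]
    YA_T[[qi]] <- yA; YB_T[[qi]] <- yB
    YAB_T[[qi]] <- lapply(seq_len(n_p), function(i) Y[n_t, idxAB(i)])
    for (i in seq_len(n_p)) {
      if (collapsed[i]) {
        ci[, qi, i] <- c(0, 0)
        next
      }
      ci[, qi, i] <- bootstrap_ci(yA, yB, YAB_T[[qi]][[i]], n_boot = n_boot,
                                  seed = seed + i)
      influential[qi, i] <- ST[n_t, qi, i] > eps_s
    }
  }

  structure(
    list(
      times = res$times,
      ST = ST,
      ci = ci,
      influential = influential,
      eps_s = eps_s,
      space = space,
      regimen_kind = regimen$kind,
      scenario_label = scenario$label,
      n_s = n_s,
      seed = seed,
      design = design,
      YA = list(VT = YA_T[[1]], NT = YA_T[[2]]),
      YB = list(VT = YB_T[[1]], NT = YB_T[[2]]),
      YAB = list(VT = YAB_T[[1]], NT = YAB_T[[2]]),
      final_density = if (keep_final_density) {
        res$final[, c(idxA, idxB), drop = FALSE]
      } else NULL
    ),
    class = "sa_result"
  )
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf(
    "<sa_result> %s on %s scenario, n_s = %d (%d simulations)\n",
    x$regimen_kind, x$scenario_label, x$n_s,
    x$n_s * (nrow(x$space) + 2)
  ))
  infl <- influential_parameters(x)
  cat("influential (either QoI):", paste(infl, collapse = ", "), "\n")
  invisible(x)
}

#' Parameters flagged influential by a sensitivity analysis
#'
#' A parameter is influential when its end-of-treatment total-effects index
#' exceeds the threshold on either quantity of interest (tumor volume or
#' total cell count).
#'
#' @param sa An `sa_result`.
#' @return Character vector of parameter names, in canonical order.
#' @export
influential_parameters <- function(sa) {
  stopifnot(inherits(sa, "sa_result"))
  sa$space$name[colSums(sa$influential) > 0]
}
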