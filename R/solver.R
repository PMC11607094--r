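#' Full model parameterization
#'
#' Bundles the 15 parameters examined by the sensitivity analysis — baseline
#' diffusivity `D0`, the MuSyC pharmacodynamic parameters, the normalized
#' maximum drug concentrations and the drug decay rates — together with the
#' fixed mechanical constants. The 15 varying parameters are exposed as a
#' flat named vector in a fixed order via [as_param_vector()].
#'
#' @param D0 Baseline tumor cell diffusivity (mm^2/day, positive).
#' @param pd A [pd_params()] object.
#' @param dmax1,dmax2 Normalized maximum drug concentrations (dimensionless).
#' @param gamma1,gamma2 Drug decay rates (1/day).
#' @param mech A [mech_constants()] object.
#' @return An object of class `model_params`.
#' @export
model_params <- function(D0, pd, dmax1, dmax2, gamma1, gamma2,
                         mech = mech_constants()) {
  stopifnot(inherits(pd, "pd_params"), inherits(mech, "mech_constants"))
  if (D0 <= 0) stop("D0 must be positive", call. = FALSE)
  if (dmax1 < 0 || dmax2 < 0) stop("dmax must be non-negative", call. = FALSE)
  if (gamma1 <= 0 || gamma2 <= 0) stop("decay rates must be positive", call. = FALSE)
  structure(
    list(D0 = D0, pd = pd, dmax1 = dmax1, dmax2 = dmax2,
         gamma1 = gamma1, gamma2 = gamma2, mech = mech),
    class = "model_params"
  )
}

#' Fixed order of the 15 sensitivity-analysis parameters
#' @export
PARAM_NAMES <- c("D0", "rho0", "h1", "h2", "C1", "C2", "E1n", "E2n",
                 "a1", "a2", "beta", "dmax1", "dmax2", "gamma1", "gamma2")

#' Flatten model parameters to the canonical 15-vector
#'
#' @param params A [model_params()] object.
#' @return A named numeric vector in the order of [PARAM_NAMES].
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "model_params"))
  p <- params$pd
  c(D0 = params$D0, rho0 = p$rho0, h1 = p$h1, h2 = p$h2, C1 = p$C1,
    C2 = p$C2, E1n = p$E1n, E2n = p$E2n, a1 = p$a1, a2 = p$a2,
    beta = p$beta, dmax1 = params$dmax1, dmax2 = params$dmax2,
    gamma1 = params$gamma1, gamma2 = params$gamma2)
}

#' Rebuild model parameters from the canonical 15-vector
#'
#' @param v Named (or canonically ordered) numeric vector of length 15.
#' @param mech A [mech_constants()] object.
#' @return A [model_params()] object.
#' @export
params_from_vector <- function(v, mech = mech_constants()) {
  if (is.null(names(v))) names(v) <- PARAM_NAMES
  stopifnot(all(PARAM_NAMES %in% names(v)))
  v <- v[PARAM_NAMES]
  model_params(
    D0 = v[["D0"]],
    pd = pd_params(rho0 = v[["rho0"]], h1 = v[["h1"]], h2 = v[["h2"]],
                   C1 = v[["C1"]], C2 = v[["C2"]], E1n = v[["E1n"]],
                   E2n = v[["E2n"]], a1 = v[["a1"]], a2 = v[["a2"]],
                   beta = v[["beta"]]),
    dmax1 = v[["dmax1"]], dmax2 = v[["dmax2"]],
    gamma1 = v[["gamma1"]], gamma2 = v[["gamma2"]],
    mech = mech
  )
}

#' Mid-range model parameters for a standard regimen
#'
#' Every sensitivity-analysis parameter at the midpoint of its admissible
#' range (geometric midpoint for logarithmically sampled parameters).
#'
#' @param kind `"dox_cyc"` or `"ptx_cpt"`.
#' @param mech A [mech_constants()] object.
#' @return A [model_params()] object.
#' @export
default_params <- function(kind = c("dox_cyc", "ptx_cpt"),
                           mech = mech_constants()) {
  kind <- match.arg(kind)
  params_from_vector(space_midpoints(sa_parameter_space(kind)), mech = mech)
}

# --- low-level stepping helpers -------------------------------------------

# face-index bookkeeping for the conservative stencil: for each direction,
# the voxel indices on either side of every interior face
face_indices <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  vox <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  fx <- expand.grid(i = 1:(nx - 1), j = 1:ny, k = 1:nz)
  fy <- expand.grid(i = 1:nx, j = 1:(ny - 1), k = 1:nz)
  fz <- expand.grid(i = 1:nx, j = 1:ny, k = 1:(nz - 1))
  list(
    x = cbind(lo = vox(fx$i, fx$j, fx$k), hi = vox(fx$i + 1L, fx$j, fx$k)),
    y = cbind(lo = vox(fy$i, fy$j, fy$k), hi = vox(fy$i, fy$j + 1L, fy$k)),
    z = cbind(lo = vox(fz$i, fz$j, fz$k), hi = vox(fz$i, fz$j, fz$k + 1L))
  )
}

# face diffusivities (arithmetic mean of the voxel values, divided by the
# squared spacing) from a matrix of voxel diffusivities (n x m)
face_diffusivities <- function(Dmat, fidx, spacing) {
  list(
    x = 0.5 * (Dmat[fidx$x[, "lo"], , drop = FALSE] +
                 Dmat[fidx$x[, "hi"], , drop = FALSE]) / spacing[1]^2,
    y = 0.5 * (Dmat[fidx$y[, "lo"], , drop = FALSE] +
                 Dmat[fidx$y[, "hi"], , drop = FALSE]) / spacing[2]^2,
    z = 0.5 * (Dmat[fidx$z[, "lo"], , drop = FALSE] +
                 Dmat[fidx$z[, "hi"], , drop = FALSE]) / spacing[3]^2
  )
}

#' One implicit step of the tumor reaction-diffusion equation
#'
#' Advances the tumor cell density by one backward-Euler step of
#' `dN/dt = div(D grad N) + rho N (1 - N/theta)` with zero-flux boundaries,
#' solving the nonlinear system by Newton iteration (relative tolerance
#' 1e-8, at most 20 iterations) with a Jacobi-preconditioned conjugate
#' gradient inner solver. With `rho = 0` the step conserves total mass to
#' the Newton tolerance; with `D = 0` each voxel follows the implicit
#' logistic update.
#'
#' @param N A [scalar_field()] of tumor cell density (cells/mm^3).
#' @param D A [scalar_field()] (or scalar) diffusivity (mm^2/day).
#' @param rho A [scalar_field()] (or scalar) net proliferation rate (1/day).
#' @param dt Time step (days, positive).
#' @param theta Carrying capacity (cells/mm^3).
#' @return A [scalar_field()] with the updated density. The number of
#'   Newton iterations and the count of clipped voxels are attached as
#'   attributes `newton_iters` and `clip_count`.
#' @export
step <- function(N, D, rho, dt, theta = THETA_DEFAULT) {
  stopifnot(inherits(N, "scalar_field"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  g <- N$grid
  dvals <- if (inherits(D, "scalar_field")) D$values else array(D, dim = g$shape)
  rvals <- if (inherits(rho, "scalar_field")) rho$values else array(rho, dim = g$shape)
  if (any(dvals < 0)) stop("diffusivity must be non-negative", call. = FALSE)
  fidx <- face_indices(g$shape)
  Dm <- matrix(as.vector(dvals), ncol = 1)
  df <- face_diffusivities(Dm, fidx, g$spacing)
  res <- rd_step_cpp(as.vector(N$values), g$shape, df$x[, 1], df$y[, 1],
                     df$z[, 1], as.vector(rvals), dt, theta, 1e-8, 20L)
  out <- scalar_field(g, array(res$N, dim = g$shape))
  attr(out, "newton_iters") <- res$newton_iters
  attr(out, "clip_count") <- res$clip_count
  out
}

# dose superposition factors at each target time level for a chunk of runs:
# returns an n_t x m matrix, A[s, r] = dmax_r * sum_j exp(-gamma_r (t_s -
# t_j)) over doses delivered at or before t_s
dose_factor_matrix <- function(dose_days, dmax, gamma, times) {
  A <- matrix(0, length(times), length(dmax))
  for (tj in dose_days) {
    lag <- times - tj
    active <- lag >= 0
    if (!any(active)) next
    contrib <- exp(-outer(lag[active], gamma))
    A[active, ] <- A[active, ] + contrib
  }
  sweep(A, 2, dmax, `*`)
}

# --- batched simulation engine --------------------------------------------
#
# Advances many independent parameterizations of the model through a full
# regimen on a shared scenario. The per-run work is organised around the
# staggered scheme: at the start of every `mech_every`-step block the
# quasistatic mechanics is solved for all runs at once (one cached-Cholesky
# solve with the runs as right-hand-side columns), the stress-inhibited
# diffusivity is frozen for the block, and the reaction-diffusion steps of
# the block run in compiled code. Runs are processed in chunks to bound
# memory and keep the multi-RHS triangular solves in cache.
simulate_batch <- function(scenario, pmat, regimen, dt = 0.25,
                           mech_every = 4L, mech = mech_constants(),
                           snapshot_times = numeric(0),
                           keep_final = FALSE, chunk_size = 64L,
                           checkpoint_dir = NULL, qoi_stride = 1L) {
  stopifnot(inherits(scenario, "nac_scenario"), inherits(regimen, "nac_regimen"))
  if (is.null(rownames(pmat))) rownames(pmat) <- PARAM_NAMES
  stopifnot(nrow(pmat) == 15)
  horizon <- regimen$horizon
  nsteps <- round(horizon / dt)
  if (abs(nsteps * dt - horizon) > 1e-9 * max(1, horizon)) {
    stop("regimen horizon must be divisible by dt", call. = FALSE)
  }
  g <- scenario$grid
  n <- prod(g$shape)
  m <- ncol(pmat)
  theta <- scenario$theta
  mech <- mech_constants(E = mech$E, nu = mech$nu, gN = mech$gN, kw = mech$kw,
                         gammaN = mech$gammaN, theta = theta)
  ops <- mechanics_operators(g, mech)
  fidx <- face_indices(g$shape)
  pvec <- as.vector(scenario$p$values)
  n0 <- as.vector(scenario$N0$values)
  times <- seq(0, nsteps) * dt
  target_times <- times[-1]
  snap_steps <- integer(0)
  if (length(snapshot_times)) {
    snap_steps <- vapply(snapshot_times, function(tt) {
      s <- which.min(abs(times - tt))
      if (abs(times[s] - tt) > dt / 2 + 1e-9) {
        stop("snapshot time ", tt, " is outside the simulated horizon",
             call. = FALSE)
      }
      s - 1L
    }, integer(1))
  }
  vol <- g$voxel_volume
  nth <- theta / 4
  blocks <- split(seq_len(nsteps),
                  rep(seq_len(ceiling(nsteps / mech_every)),
                      each = mech_every)[seq_len(nsteps)])

  run_chunk <- function(cols) {
    mc <- length(cols)
    P <- pmat[, cols, drop = FALSE]
    Nmat <- matrix(n0, nrow = n, ncol = mc)
    # static MuSyC basis fields p^h1, p^h2 per run
    lgp <- ifelse(pvec > 0, log(pvec), -Inf)
    P1 <- exp(outer(lgp, P["h1", ]))
    P2 <- exp(outer(lgp, P["h2", ]))
    A1 <- dose_factor_matrix(regimen$drug1$dose_days, P["dmax1", ],
                             P["gamma1", ], target_times)
    A2 <- dose_factor_matrix(regimen$drug2$dose_days, P["dmax2", ],
                             P["gamma2", ], target_times)
    coefs <- array(0, dim = c(16, nsteps, mc))
    for (r in seq_len(mc)) {
      pd <- pd_params(rho0 = P["rho0", r], h1 = P["h1", r], h2 = P["h2", r],
                      C1 = P["C1", r], C2 = P["C2", r], E1n = P["E1n", r],
                      E2n = P["E2n", r], a1 = P["a1", r], a2 = P["a2", r],
                      beta = P["beta", r])
      coefs[, , r] <- musyc_basis_coefs(pd, A1[, r], A2[, r])
    }
    VT <- matrix(0, nsteps + 1, mc)
    NT <- matrix(0, nsteps + 1, mc)
    VT[1, ] <- colSums(Nmat >= nth) * vol
    NT[1, ] <- colSums(Nmat) * vol
    snaps <- if (length(snap_steps)) {
      lapply(seq_along(snap_steps), function(i) {
        if (snap_steps[i] == 0L) Nmat else NULL
      })
    } else list()
    for (b in blocks) {
      # mechanics from the density at the block start, then frozen D
      f <- (mech$gN / theta) * (ops$B %*% Nmat)
      U <- as.matrix(Matrix::solve(ops$chol, f))
      sv <- von_mises_u_cpp(U, Nmat, g$shape, g$spacing, mech$lambda,
                            mech$mu, mech$gN / theta)
      ns <- length(b)
      cf <- coefs[, b, , drop = FALSE]
      keep_all <- length(snap_steps) && any(snap_steps %in% b)
      out <- advance_block_cpp(Nmat, g$shape, sv, P["D0", ], mech$gammaN,
                               g$spacing, P1, P2, as.vector(cf), ns, dt,
                               theta, 1e-8, 20L, nth, vol, keep_all)
      VT[b + 1L, ] <- out$VT
      NT[b + 1L, ] <- out$NT
      if (keep_all) {
        for (s in seq_len(ns)) {
          hit <- which(snap_steps == b[s])
          for (i in hit) {
            snaps[[i]] <- matrix(out$all[n * mc * (s - 1) + seq_len(n * mc)],
                                 nrow = n)
          }
        }
      }
      Nmat <- out$N
    }
    list(VT = VT, NT = NT,
         final = if (keep_final) Nmat else NULL,
         snaps = snaps)
  }

  chunk_starts <- seq(1, m, by = chunk_size)
  results <- vector("list", length(chunk_starts))
  for (ci in seq_along(chunk_starts)) {
    cols <- chunk_starts[ci]:min(chunk_starts[ci] + chunk_size - 1, m)
    if (!is.null(checkpoint_dir)) {
      ck <- file.path(checkpoint_dir, sprintf("chunk_%05d.rds", ci))
      if (file.exists(ck)) {
        results[[ci]] <- readRDS(ck)
        next
      }
      results[[ci]] <- run_chunk(cols)
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(results[[ci]], ck)
    } else {
      results[[ci]] <- run_chunk(cols)
    }
  }
  keep_rows <- unique(c(seq(1, nsteps + 1, by = qoi_stride), nsteps + 1))
  out <- list(
    times = times[keep_rows],
    VT = do.call(cbind, lapply(results, function(r) r$VT[keep_rows, , drop = FALSE])),
    NT = do.call(cbind, lapply(results, function(r) r$NT[keep_rows, , drop = FALSE])),
    final = if (keep_final) do.call(cbind, lapply(results, `[[`, "final")) else NULL,
    snapshots = if (length(snap_steps)) {
      lapply(seq_along(snap_steps), function(i) {
        do.call(cbind, lapply(results, function(r) r$snaps[[i]]))
      })
    } else NULL,
    snapshot_times = if (length(snap_steps)) times[snap_steps + 1L] else numeric(0)
  )
  out
}

#' Simulate the mechanically coupled model through a regimen
#'
#' Runs the full coupled model on a scenario: every `mech_every` time steps
#' (starting at t = 0) the quasistatic mechanical equilibrium is solved from
#' the current density and the stress-inhibited diffusivity is refreshed;
#' every step the perfusion-weighted drug concentrations and the MuSyC
#' proliferation rate are evaluated at the target time level and the density
#' advances by one implicit step.
#'
#' @param scenario An `nac_scenario`.
#' @param params A [model_params()] object.
#' @param regimen An `nac_regimen`; its calendar is used while the
#'   per-drug `dmax`/`gamma` come from `params`.
#' @param dt Time step (days); the horizon must be divisible by it.
#' @param mech_every Number of steps between mechanics solves.
#' @param snapshot_times Times (days) at which to store density snapshots.
#' @return An object of class `nac_trajectory`: `times`, a `qoi` tibble with
#'   columns `time`, `VT` (tumor volume, mm^3), `NT` (total cells), and
#'   `snapshots` (named list of [scalar_field()]s).
#' @examples
#' \donttest{
#' sc <- synth_scenario(make_grid(c(8, 8, 8), 3), tumor_radius_mm = 6, seed = 1)
#' traj <- simulate(sc, default_params("dox_cyc"), standard_regimen("dox_cyc"))
#' }
#' @export
simulate <- function(scenario, params, regimen, dt = 0.25, mech_every = 4L,
                     snapshot_times = numeric(0)) {
  stopifnot(inherits(params, "model_params"))
  pmat <- matrix(as_param_vector(params), ncol = 1,
                 dimnames = list(PARAM_NAMES, NULL))
  res <- simulate_batch(scenario, pmat, regimen, dt = dt,
                        mech_every = mech_every, mech = params$mech,
                        snapshot_times = snapshot_times, keep_final = TRUE)
  snaps <- NULL
  if (!is.null(res$snapshots)) {
    snaps <- lapply(res$snapshots, function(s) {
      scalar_field(scenario$grid, array(s[, 1], dim = scenario$grid$shape))
    })
    names(snaps) <- sprintf("t=%g", res$snapshot_times)
  }
  structure(
    list(
      times = res$times,
      qoi = tibble::tibble(time = res$times, VT = res$VT[, 1], NT = res$NT[, 1]),
      final = scalar_field(scenario$grid,
                           array(res$final[, 1], dim = scenario$grid$shape)),
      snapshots = snaps,
      scenario_label = scenario$label,
      regimen_kind = regimen$kind,
      theta = scenario$theta
    ),
    class = "nac_trajectory"
  )
}

#' @export
print.nac_trajectory <- function(x, ...) {
  cat(sprintf(
    "<nac_trajectory> %s on %s scenario: %d steps to t = %g days\n",
    x$regimen_kind, x$scenario_label, length(x$times) - 1, max(x$times)
  ))
  last <- x$qoi[nrow(x$qoi), ]
  cat(sprintf("  V_T(T) = %.4g mm^3, N_T(T) = %.4g cells\n", last$VT, last$NT))
  invisible(x)
}

#' Export a trajectory to a directory of plain files
#'
#' Writes the quantity-of-interest series as CSV, the snapshot times and
#' metadata as JSON, and each stored density snapshot as a NIfTI volume.
#'
#' @param traj An `nac_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "nac_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(traj$qoi, file.path(dir, "qoi.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(regimen = traj$regimen_kind, scenario = traj$scenario_label,
         theta = traj$theta,
         snapshot_times = names(traj$snapshots)),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(traj$snapshots)) {
    for (nm in names(traj$snapshots)) {
      fn <- file.path(dir, paste0(gsub("[^0-9a-zA-Z.]", "_", nm), ".nii.gz"))
      write_volume(traj$snapshots[[nm]], fn)
    }
  }
  write_volume(traj$final, file.path(dir, "final.nii.gz"))
  invisible(dir)
}
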