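#' Tumor volume of a density field
#'
#' The volume of the region where the tumor cell density reaches the
#' segmentation threshold `N_th = theta / 4` (the density level that
#' delineates tumor from healthy tissue in imaging-derived maps), computed
#' by midpoint quadrature: the count of voxels at or above the threshold
#' times the voxel volume. A voxel exactly at the threshold counts as tumor.
#'
#' @param N A [scalar_field()] of tumor cell density.
#' @param theta Carrying capacity (cells/mm^3).
#' @param threshold Segmentation threshold; defaults to `theta / 4`.
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(N, theta = THETA_DEFAULT, threshold = theta / 4) {
  stopifnot(inherits(N, "scalar_field"))
  sum(N$values >= threshold) * N$grid$voxel_volume
}

#' Total tumor cell count of a density field
#'
#' Midpoint-quadrature integral of the density over the tissue box:
#' the sum of voxel values times the voxel volume.
#'
#' @param N A [scalar_field()] of tumor cell density.
#' @return Total number of tumor cells.
#' @export
total_cells <- function(N) {
  stopifnot(inherits(N, "scalar_field"))
  sum(N$values) * N$grid$voxel_volume
}

#' Mean relative difference of a density map against a reference
#'
#' The signed average of `(N - N_ref) / N_ref` over the reference tumor
#' region (voxels where the reference density reaches `theta / 4`),
#' normalized by the reference tumor volume: zero when the maps agree on
#' the reference region, -1 when the tumor has been eliminated there.
#'
#' @param N A [scalar_field()] of tumor cell density.
#' @param N_ref The reference density field on the same grid.
#' @param theta Carrying capacity (cells/mm^3).
#' @return The mean relative difference (dimensionless).
#' @export
mrd <- function(N, N_ref, theta = THETA_DEFAULT) {
  stopifnot(inherits(N, "scalar_field"), inherits(N_ref, "scalar_field"))
  if (!identical(dim(N$values), dim(N_ref$values))) {
    stop("fields must share a grid", call. = FALSE)
  }
  nth <- theta / 4
  mask <- N_ref$values >= nth
  vt_ref <- sum(mask) * N$grid$voxel_volume
  if (vt_ref <= 0) {
    stop("reference tumor region is empty; MRD is undefined", call. = FALSE)
  }
  sum((N$values[mask] - N_ref$values[mask]) / N_ref$values[mask]) *
    N$grid$voxel_volume / vt_ref
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length (at least 2) with nonzero
#'   variance.
#' @return Pearson's r.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement metric penalizing both dispersion and location shifts:
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, using
#' population (1/n) moments. Always bounded by the absolute Pearson
#' correlation.
#'
#' @inheritParams pcc
#' @return The concordance correlation coefficient.
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 || vy == 0) {
    stop("concordance undefined for constant input", call. = FALSE)
  }
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

.reference_cache <- new.env(parent = emptyenv())

#' No-treatment reference simulation
#'
#' Runs the model with no drug exposure and the baseline literature values
#' `D0 = 2e-4` mm^2/day, `rho0 = 2.5e-2` 1/day on the given scenario, used
#' as the fixed reference for mean-relative-difference comparisons. The
#' result is cached per (scenario, horizon, dt), so repeated calls reuse
#' the same trajectory.
#'
#' @param scenario An `nac_scenario`.
#' @param horizon Time horizon in days (e.g. the regimen length).
#' @param dt Time step (days).
#' @param mech_every Steps between mechanics solves.
#' @param mech Mechanical constants.
#' @return An `nac_trajectory` with the final density in `$final`.
#' @export
reference_run <- function(scenario, horizon = 56, dt = 0.25, mech_every = 4L,
                          mech = mech_constants()) {
  stopifnot(inherits(scenario, "nac_scenario"))
  key <- digest::digest(list(scenario, horizon, dt, mech_every,
                             mech[c("E", "nu", "gN", "kw", "gammaN")]))
  if (!is.null(.reference_cache[[key]])) return(.reference_cache[[key]])
  pd <- pd_params(rho0 = 2.5e-2, h1 = 1, h2 = 1, C1 = 1, C2 = 1,
                  E1n = 0, E2n = 0, a1 = 1, a2 = 1, beta = 0)
  params <- model_params(D0 = 2e-4, pd = pd, dmax1 = 0, dmax2 = 0,
                         gamma1 = 1, gamma2 = 1, mech = mech)
  # a drug-free calendar: dmax = 0 makes the dose days irrelevant
  reg <- new_regimen(
    drug_spec("none1", 0, 0, 1), drug_spec("none2", 0, 0, 1),
    horizon = horizon, kind = "no_treatment"
  )
  traj <- simulate(scenario, params, reg, dt = dt, mech_every = mech_every)
  .reference_cache[[key]] <- traj
  traj
}
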