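#' Tissue-box carrying capacity and fixed mechanical constants
#'
#' The carrying capacity of breast tissue used throughout the package,
#' in cells/mm^3. This is the maximum admissible tumor cell density.
#' @export
THETA_DEFAULT <- 2.02e6

#' Synthetic tumor scenario
#'
#' Bundles the initial tumor cell density `N0` (cells/mm^3) and the static,
#' normalized perfusion map `p` (in `[0, 1]`) on a common grid. Scenarios
#' stand in for imaging-derived tissue boxes: an ellipsoidal tumor embedded
#' in a ring of healthy tissue, with either uniformly high perfusion
#' ("well-perfused") or perfusion suppressed in the tumor core
#' ("poorly-perfused").
#'
#' @param grid A [make_grid()] object.
#' @param N0 A [scalar_field()] of initial tumor cell density.
#' @param p A [scalar_field()] of normalized perfusion.
#' @param label One of `"well_perfused"`, `"poorly_perfused"`, `"custom"`.
#' @param theta Carrying capacity (cells/mm^3).
#' @return An object of class `nac_scenario`.
#' @export
new_scenario <- function(grid, N0, p, label = "custom", theta = THETA_DEFAULT) {
  stopifnot(inherits(grid, "nac_grid"), inherits(N0, "scalar_field"),
            inherits(p, "scalar_field"))
  label <- match.arg(label, c("well_perfused", "poorly_perfused", "custom"))
  if (any(N0$values < 0) || any(N0$values > theta)) {
    stop("initial density must lie in [0, theta]", call. = FALSE)
  }
  if (any(p$values < 0) || any(p$values > 1)) {
    stop("perfusion must lie in [0, 1]", call. = FALSE)
  }
  if (tumor_touches_boundary(N0$values, theta / 4)) {
    stop("tumor region (N0 > theta/4) must not touch the box boundary",
         call. = FALSE)
  }
  structure(
    list(grid = grid, N0 = N0, p = p, label = label, theta = theta),
    class = "nac_scenario"
  )
}

tumor_touches_boundary <- function(v, threshold) {
  d <- dim(v)
  any(v[c(1, d[1]), , ] > threshold) ||
    any(v[, c(1, d[2]), ] > threshold) ||
    any(v[, , c(1, d[3])] > threshold)
}

#' @export
print.nac_scenario <- function(x, ...) {
  cat(sprintf(
    "<nac_scenario> %s, %d x %d x %d voxels, peak N0/theta = %.3f, p in [%.2f, %.2f]\n",
    x$label, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    max(x$N0$values) / x$theta, min(x$p$values), max(x$p$values)
  ))
  invisible(x)
}

#' Generate a synthetic tumor scenario
#'
#' Builds an ellipsoidal tumor of the given radius at the box centre with
#' density `peak_density_fraction * theta`, smoothed by a Gaussian of width
#' `smooth_mm` and clipped to `[0, theta]`. The perfusion map is a high
#' plateau (default 0.9) with small seeded spatial noise; for
#' `perfusion = "poor"` the plateau is smoothly suppressed (default to 0.2)
#' inside the tumor core. Generation is bit-reproducible for a given seed.
#'
#' The perfusion plateau and core suppression levels straddle the contrast
#' seen between normalized perfusion maps of well- and poorly-perfused
#' breast tumors; the initial peak density default of `0.6 * theta` is a
#' mid-range cellularity for an untreated tumor.
#'
#' @param grid A [make_grid()] object.
#' @param tumor_radius_mm Tumor semi-axis length in mm (sphere by default; a
#'   length-3 vector gives an ellipsoid).
#' @param peak_density_fraction Initial tumor density as a fraction of the
#'   carrying capacity, in `(0, 1]`.
#' @param perfusion `"well"` or `"poor"`.
#' @param smooth_mm Gaussian smoothing width (standard deviation, mm)
#'   applied to the density and to the core suppression blend.
#' @param seed Integer seed for the perfusion noise.
#' @param plateau Perfusion plateau outside (and, if well-perfused, inside)
#'   the tumor.
#' @param core_level Suppressed perfusion level in the tumor core
#'   (poorly-perfused scenarios).
#' @param noise_amplitude Standard deviation of the seeded perfusion noise.
#' @param theta Carrying capacity (cells/mm^3).
#' @return An `nac_scenario`.
#' @examples
#' g <- make_grid(c(16, 16, 16), 2)
#' sc <- synth_scenario(g, tumor_radius_mm = 8, seed = 1)
#' @export
synth_scenario <- function(grid,
                           tumor_radius_mm = 8,
                           peak_density_fraction = 0.6,
                           perfusion = c("well", "poor"),
                           smooth_mm = 2,
                           seed = 1L,
                           plateau = 0.9,
                           core_level = 0.2,
                           noise_amplitude = 0.02,
                           theta = THETA_DEFAULT) {
  stopifnot(inherits(grid, "nac_grid"))
  perfusion <- match.arg(perfusion)
  radius <- rep(as.numeric(tumor_radius_mm), length.out = 3)
  if (any(radius <= 0)) stop("tumor radius must be positive", call. = FALSE)
  if (peak_density_fraction <= 0 || peak_density_fraction > 1) {
    stop("peak_density_fraction must be in (0, 1]", call. = FALSE)
  }
  if (smooth_mm < 0) stop("smooth_mm must be non-negative", call. = FALSE)

  ax <- grid_axes(grid)
  centre <- vapply(ax, function(a) mean(range(a)), numeric(1))
  # require a healthy margin of at least 2 voxels between the tumor surface
  # and each box face
  half_extent <- (grid$shape - 1) * grid$spacing / 2
  if (any(radius + 2 * grid$spacing > half_extent)) {
    stop("tumor does not fit inside the grid with a 2-voxel healthy margin",
         call. = FALSE)
  }

  r2 <- outer(
    outer(((ax$x - centre[1]) / radius[1])^2, ((ax$y - centre[2]) / radius[2])^2, "+"),
    ((ax$z - centre[3]) / radius[3])^2, "+"
  )
  inside <- array(as.numeric(r2 <= 1), dim = grid$shape)

  n0 <- peak_density_fraction * theta * inside
  n0 <- gaussian_smooth(n0, grid$spacing, smooth_mm)
  n0 <- pmin(pmax(n0, 0), theta)
  n0 <- array(n0, dim = grid$shape)

  noise <- withr::with_seed(
    seed, array(stats::rnorm(prod(grid$shape), sd = 1), dim = grid$shape)
  )
  noise <- gaussian_smooth(noise, grid$spacing, max(smooth_mm, min(grid$spacing)))
  if (noise_amplitude > 0 && stats::sd(noise) > 0) {
    noise <- noise_amplitude * noise / stats::sd(noise)
  } else {
    noise <- array(0, dim = grid$shape)
  }

  p <- array(plateau, dim = grid$shape) + noise
  if (perfusion == "poor") {
    core <- gaussian_smooth(inside, grid$spacing, smooth_mm)
    core <- pmin(pmax(core, 0), 1)
    p <- p - (plateau - core_level) * core
  }
  p <- pmin(pmax(p, 0), 1)

  new_scenario(
    grid,
    scalar_field(grid, n0),
    scalar_field(grid, p),
    label = if (perfusion == "well") "well_perfused" else "poorly_perfused",
    theta = theta
  )
}

#' Write a scenario as a pair of NIfTI volumes
#'
#' Writes `<stem>_N0.nii.gz` and `<stem>_perfusion.nii.gz` plus a small JSON
#' sidecar `<stem>.json` recording the label and carrying capacity.
#'
#' @param scenario An `nac_scenario`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_scenario <- function(scenario, stem) {
  stopifnot(inherits(scenario, "nac_scenario"))
  write_volume(scenario$N0, paste0(stem, "_N0.nii.gz"))
  write_volume(scenario$p, paste0(stem, "_perfusion.nii.gz"))
  jsonlite::write_json(
    list(label = scenario$label, theta = scenario$theta),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Read a scenario written by [write_scenario()]
#'
#' @param stem Path stem used when writing.
#' @return An `nac_scenario`.
#' @export
read_scenario <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  n0 <- read_volume(paste0(stem, "_N0.nii.gz"))
  p <- read_volume(paste0(stem, "_perfusion.nii.gz"))
  new_scenario(n0$grid, n0, p, label = meta$label, theta = meta$theta)
}
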