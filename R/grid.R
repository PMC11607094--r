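#' Structured voxel grid
#'
#' A `nac_grid` describes the regular voxel lattice of a tissue box: the
#' number of voxels per axis, the voxel spacing in millimetres, and the
#' position of the first voxel centre. All fields in the package live on such
#' a grid, with values attached to voxel centres.
#'
#' @param shape Integer vector of length 3, voxels per axis. Every entry must
#'   be at least 4 so that a tumor with a healthy margin fits in the box.
#' @param spacing_mm Positive numeric vector of length 3 (or a scalar,
#'   recycled), voxel spacing in mm per axis.
#' @param origin Numeric vector of length 3, coordinates of the first voxel
#'   centre in mm. Defaults to the origin.
#'
#' @return An object of class `nac_grid` with elements `shape`, `spacing`,
#'   `origin`, and the derived `voxel_volume` (mm^3).
#' @examples
#' g <- make_grid(c(16, 16, 16), c(2, 2, 2))
#' g$voxel_volume # 8 mm^3
#' @export
make_grid <- function(shape, spacing_mm, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) == 1) shape <- rep(shape, 3L)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(shape) == 3, length(spacing_mm) == 3, length(origin) == 3)
  if (any(!is.finite(shape)) || any(shape < 4L)) {
    stop("every grid dimension must have at least 4 voxels", call. = FALSE)
  }
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("voxel spacing must be positive", call. = FALSE)
  }
  structure(
    list(
      shape = shape,
      spacing = as.numeric(spacing_mm),
      origin = as.numeric(origin),
      voxel_volume = prod(spacing_mm)
    ),
    class = "nac_grid"
  )
}

#' @export
print.nac_grid <- function(x, ...) {
  cat(sprintf(
    "<nac_grid> %d x %d x %d voxels, spacing %s mm, voxel volume %.4g mm^3\n",
    x$shape[1], x$shape[2], x$shape[3],
    paste(signif(x$spacing, 4), collapse = " x "), x$voxel_volume
  ))
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid A [make_grid()] object.
#' @return A list with numeric vectors `x`, `y`, `z` of axis coordinates (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "nac_grid"))
  list(
    x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
    y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
    z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  )
}

#' Scalar field on a voxel grid
#'
#' Wraps a 3-D numeric array of per-voxel values together with its grid.
#' Used for tumor cell density N (cells/mm^3), perfusion p (dimensionless),
#' von Mises stress (kPa) and diffusivity (mm^2/day).
#'
#' @param grid A [make_grid()] object.
#' @param values Numeric array whose dimension equals `grid$shape`, or a
#'   scalar which is recycled over the grid.
#' @return An object of class `scalar_field` with elements `grid` and
#'   `values`.
#' @export
scalar_field <- function(grid, values) {
  stopifnot(inherits(grid, "nac_grid"))
  if (length(values) == 1) {
    values <- array(as.numeric(values), dim = grid$shape)
  }
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape))) {
    stop("value array shape does not match grid shape", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("scalar field values must be finite", call. = FALSE)
  }
  structure(list(grid = grid, values = values), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  r <- range(x$values)
  cat(sprintf(
    "<scalar_field> %d x %d x %d, range [%.4g, %.4g]\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], r[1], r[2]
  ))
  invisible(x)
}

#' Convert a scalar field to a tibble of voxel records
#'
#' One row per voxel with its centre coordinates and value, convenient for
#' dplyr/ggplot2 work on slices.
#'
#' @param x A [scalar_field()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z` (mm) and `value`.
#' @export
as_tibble.scalar_field <- function(x, ...) {
  ax <- grid_axes(x$grid)
  vals <- as.vector(x$values)
  tibble::tibble(
    x = rep(ax$x, times = length(ax$y) * length(ax$z)),
    y = rep(rep(ax$y, each = length(ax$x)), times = length(ax$z)),
    z = rep(ax$z, each = length(ax$x) * length(ax$y)),
    value = vals
  )
}

#' Trilinear upsampling of a scalar field
#'
#' Refines a field onto a grid with `factor`-times finer spacing using
#' trilinear interpolation. The refined grid keeps the original voxel centres
#' as every `factor`-th node, so sampling the result at the original nodes
#' reproduces the original values exactly, and interpolated values never
#' leave the range of the input (the interpolation is convex).
#'
#' @param field A [scalar_field()].
#' @param factor Integer refinement factor, at least 1. `factor = 1` returns
#'   the field unchanged.
#' @return A [scalar_field()] on the refined grid with shape
#'   `(n - 1) * factor + 1` per axis and spacing `spacing / factor`.
#' @export
upsample <- function(field, factor) {
  stopifnot(inherits(field, "scalar_field"))
  factor <- as.integer(factor)
  if (length(factor) != 1 || is.na(factor) || factor < 1L) {
    stop("upsampling factor must be an integer >= 1", call. = FALSE)
  }
  if (factor == 1L) return(field)
  g <- field$grid
  new_shape <- (g$shape - 1L) * factor + 1L
  new_grid <- make_grid(new_shape, g$spacing / factor, g$origin)
  # separable 1-D linear interpolation along each axis in turn
  interp_axis <- function(arr, axis) {
    n <- dim(arr)[axis]
    # fractional source positions for the refined axis
    pos <- (seq_len((n - 1L) * factor + 1L) - 1) / factor + 1
    i0 <- pmin(floor(pos), n - 1)
    w <- pos - i0
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    out <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1, , drop = FALSE] * w
    out <- array(out, dim = c(length(pos), d[2], d[3]))
    aperm(out, order(perm))
  }
  v <- field$values
  for (ax in 1:3) v <- interp_axis(v, ax)
  scalar_field(new_grid, v)
}

# Separable Gaussian smoothing on a voxel grid (reflecting boundaries).
# width_mm is the standard deviation of the kernel in mm; width 0 is the
# identity. Implemented as three small dense 1-D smoothing operators so the
# result is deterministic and exactly mass-preserving per axis up to the
# boundary reflection.
gaussian_smooth <- function(values, spacing, width_mm) {
  if (width_mm <= 0) return(values)
  smooth_axis <- function(arr, axis) {
    n <- dim(arr)[axis]
    h <- spacing[axis]
    sd_vox <- width_mm / h
    half <- max(1L, ceiling(3 * sd_vox))
    k <- stats::dnorm(seq(-half, half), sd = sd_vox)
    k <- k / sum(k)
    # dense 1-D operator with reflecting boundary
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + seq(-half, half)
      idx <- ifelse(idx < 1, 2 - idx, idx)
      idx <- ifelse(idx > n, 2 * n - idx, idx)
      for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + k[j]
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    out <- S %*% matrix(a, nrow = d[1])
    aperm(array(out, d), order(perm))
  }
  for (ax in 1:3) values <- smooth_axis(values, ax)
  values
}
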