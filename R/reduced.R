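#' Compare the original model against a reduced parameterization
#'
#' The reduced model varies only the influential parameters identified by a
#' sensitivity analysis while all remaining parameters are fixed (by
#' default at the midpoints of their admissible ranges, geometric for
#' log-sampled parameters). For each selected row of the base sample
#' matrices A and B, both the original (all 15 parameters from the row) and
#' the reduced model are run to the end of treatment; the paired tumor
#' volumes, total cell counts and — when requested — mean relative
#' differences against the no-treatment reference are returned together
#' with their Pearson and concordance correlations.
#'
#' @param scenario An `nac_scenario`.
#' @param sa An `sa_result` from [run_sa()] (carries the design, ranges,
#'   influence labels and, if kept, the original-model end-of-treatment
#'   outcomes, which are then reused instead of re-simulated).
#' @param influential Character vector of parameter names allowed to vary
#'   in the reduced model; defaults to the SA influence labels.
#' @param fixed_values Named vector of values for the frozen parameters;
#'   defaults to range midpoints.
#' @param rows Indices into the stacked `rbind(A, B)` sample (2 n_s rows);
#'   defaults to all of them.
#' @param compute_mrd Also compute the mean relative difference of each
#'   run's final density map against the no-treatment reference (requires
#'   `keep_final_density = TRUE` in [run_sa()] to avoid re-running the
#'   original model).
#' @param dt,mech_every Solver settings (should match the SA campaign).
#' @param chunk_size Runs per solver chunk.
#' @return A tibble of class `reduced_comparison` with one row per sampled
#'   parameter combination and columns `row`, `VT_orig`, `VT_red`,
#'   `NT_orig`, `NT_red` (and `MRD_orig`, `MRD_red`); summary correlations
#'   via [glance.reduced_comparison()].
#' @export
reduced_model_comparison <- function(scenario, sa,
                                     influential = NULL,
                                     fixed_values = NULL,
                                     rows = NULL,
                                     compute_mrd = FALSE,
                                     dt = 0.25, mech_every = 4L,
                                     chunk_size = 64L) {
  stopifnot(inherits(scenario, "nac_scenario"), inherits(sa, "sa_result"))
  space <- sa$space
  if (is.null(influential)) influential <- influential_parameters(sa)
  if (!length(influential)) {
    stop("the influential parameter set is empty", call. = FALSE)
  }
  if (!all(influential %in% space$name)) {
    stop("unknown parameter in 'influential'", call. = FALSE)
  }
  if (is.null(fixed_values)) fixed_values <- space_midpoints(space)
  sample_mat <- rbind(sa$design$A, sa$design$B)
  if (is.null(rows)) rows <- seq_len(nrow(sample_mat))
  sel <- sample_mat[rows, , drop = FALSE]
  regimen <- standard_regimen(sa$regimen_kind)

  reduced <- sel
  frozen <- setdiff(space$name, influential)
  for (nm in frozen) reduced[, nm] <- fixed_values[[nm]]

  res_red <- simulate_batch(scenario, t(reduced), regimen, dt = dt,
                            mech_every = mech_every,
                            keep_final = compute_mrd,
                            chunk_size = chunk_size)
  n_t <- length(res_red$times)

  have_orig <- !is.null(sa$final_density) || !compute_mrd
  if (!is.null(sa$YA) && max(rows) <= 2 * sa$n_s && have_orig) {
    yA <- c(sa$YA$VT, sa$YB$VT)
    yN <- c(sa$YA$NT, sa$YB$NT)
    VT_orig <- yA[rows]
    NT_orig <- yN[rows]
    final_orig <- if (compute_mrd) sa$final_density[, rows, drop = FALSE]
  } else {
    res_orig <- simulate_batch(scenario, t(sel), regimen, dt = dt,
                               mech_every = mech_every,
                               keep_final = compute_mrd,
                               chunk_size = chunk_size)
    VT_orig <- res_orig$VT[n_t, ]
    NT_orig <- res_orig$NT[n_t, ]
    final_orig <- if (compute_mrd) res_orig$final
  }

  out <- tibble::tibble(
    row = rows,
    VT_orig = VT_orig, VT_red = res_red$VT[n_t, ],
    NT_orig = NT_orig, NT_red = res_red$NT[n_t, ]
  )
  if (compute_mrd) {
    ref <- reference_run(scenario, horizon = regimen$horizon, dt = dt,
                         mech_every = mech_every)
    grid <- scenario$grid
    as_field <- function(v) scalar_field(grid, array(v, dim = grid$shape))
    out$MRD_orig <- vapply(seq_along(rows), function(i) {
      mrd(as_field(final_orig[, i]), ref$final, theta = scenario$theta)
    }, numeric(1))
    out$MRD_red <- vapply(seq_along(rows), function(i) {
      mrd(as_field(res_red$final[, i]), ref$final, theta = scenario$theta)
    }, numeric(1))
  }
  attr(out, "influential") <- influential
  attr(out, "fixed_values") <- fixed_values[frozen]
  attr(out, "regimen_kind") <- sa$regimen_kind
  class(out) <- c("reduced_comparison", class(out))
  out
}
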