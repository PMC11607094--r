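#' Drug specification for a chemotherapy schedule
#'
#' Describes one drug of a two-drug neoadjuvant regimen: its bolus delivery
#' days, the normalized maximum concentration reached at each delivery
#' (`dmax_norm`, the nominal peak concentration divided by the drug's
#' half-maximal effective concentration), and the exponential decay rate of
#' its terminal pharmacokinetic phase.
#'
#' @param name Drug name.
#' @param dose_days Strictly increasing numeric vector of delivery times
#'   (days from the start of treatment).
#' @param dmax_norm Normalized maximum concentration per dose
#'   (dimensionless, non-negative).
#' @param decay Exponential decay rate (1/day, positive).
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(name, dose_days, dmax_norm, decay) {
  dose_days <- as.numeric(dose_days)
  if (length(dose_days) < 1 || any(diff(dose_days) <= 0)) {
    stop("dose_days must be non-empty and strictly increasing", call. = FALSE)
  }
  if (!is.finite(dmax_norm) || dmax_norm < 0) {
    stop("dmax_norm must be non-negative", call. = FALSE)
  }
  if (!is.finite(decay) || decay <= 0) {
    stop("decay rate must be positive", call. = FALSE)
  }
  structure(
    list(name = name, dose_days = dose_days,
         dmax_norm = as.numeric(dmax_norm), decay = as.numeric(decay)),
    class = "drug_spec"
  )
}

#' Two-drug regimen
#'
#' @param drug1,drug2 [drug_spec()] objects.
#' @param horizon Treatment horizon T in days; all doses must fall before T.
#' @param kind Optional label (`"dox_cyc"`, `"ptx_cpt"` or `"custom"`).
#' @return An object of class `nac_regimen`.
#' @export
new_regimen <- function(drug1, drug2, horizon, kind = "custom") {
  stopifnot(inherits(drug1, "drug_spec"), inherits(drug2, "drug_spec"))
  if (any(drug1$dose_days >= horizon) || any(drug2$dose_days >= horizon)) {
    stop("all dose days must fall strictly before the horizon", call. = FALSE)
  }
  structure(
    list(drug1 = drug1, drug2 = drug2, horizon = as.numeric(horizon),
         kind = kind),
    class = "nac_regimen"
  )
}

#' @export
print.nac_regimen <- function(x, ...) {
  cat(sprintf(
    "<nac_regimen> %s: %s (%d doses), %s (%d doses), T = %g days\n",
    x$kind, x$drug1$name, length(x$drug1$dose_days),
    x$drug2$name, length(x$drug2$dose_days), x$horizon
  ))
  invisible(x)
}

#' Standard neoadjuvant chemotherapy calendars
#'
#' `dox_cyc`: doxorubicin plus cyclophosphamide, four 2-week cycles with both
#' drugs delivered on the first day of each cycle (days 0, 14, 28, 42;
#' T = 56 days). `ptx_cpt`: paclitaxel plus carboplatin, four 3-week cycles
#' with paclitaxel delivered weekly (days 0, 7, ..., 77; 12 doses) and
#' carboplatin on the first day of each cycle (days 0, 21, 42, 63;
#' T = 84 days).
#'
#' The normalized peak concentrations and decay rates default to the
#' mid-range values of the sensitivity-analysis parameter space for the
#' chosen regimen (see [sa_parameter_space()]); pass `dmax_norm`/`decay` to
#' override them.
#'
#' @param kind `"dox_cyc"` or `"ptx_cpt"`.
#' @param dmax_norm Length-2 numeric, normalized maximum concentration per
#'   drug.
#' @param decay Length-2 numeric, decay rates (1/day) per drug.
#' @return An `nac_regimen`.
#' @examples
#' standard_regimen("dox_cyc")
#' @export
standard_regimen <- function(kind = c("dox_cyc", "ptx_cpt"),
                             dmax_norm = NULL, decay = NULL) {
  kind <- match.arg(kind)
  space <- sa_parameter_space(kind)
  mids <- space_midpoints(space)
  if (is.null(dmax_norm)) dmax_norm <- c(mids[["dmax1"]], mids[["dmax2"]])
  if (is.null(decay)) decay <- c(mids[["gamma1"]], mids[["gamma2"]])
  if (kind == "dox_cyc") {
    d1 <- drug_spec("doxorubicin", seq(0, 42, by = 14), dmax_norm[1], decay[1])
    d2 <- drug_spec("cyclophosphamide", seq(0, 42, by = 14), dmax_norm[2], decay[2])
    new_regimen(d1, d2, horizon = 56, kind = kind)
  } else {
    d1 <- drug_spec("paclitaxel", seq(0, 77, by = 7), dmax_norm[1], decay[1])
    d2 <- drug_spec("carboplatin", seq(0, 63, by = 21), dmax_norm[2], decay[2])
    new_regimen(d1, d2, horizon = 84, kind = kind)
  }
}

#' Scalar dose-superposition factor of a drug at time t
#'
#' The sum over past (and current) doses of `dmax_norm * exp(-decay * (t -
#' t_j))`. A dose contributes from its delivery instant inclusive, so the
#' factor jumps by `dmax_norm` exactly at each dose day. The spatial
#' normalized concentration field is this factor times the perfusion map.
#'
#' @param drug A [drug_spec()].
#' @param t Non-negative time(s) in days; vectorized.
#' @return Numeric vector of superposition factors, one per time.
#' @export
dose_factor <- function(drug, t) {
  stopifnot(inherits(drug, "drug_spec"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  vapply(t, function(tt) {
    active <- drug$dose_days <= tt
    sum(drug$dmax_norm * exp(-drug$decay * (tt - drug$dose_days[active])))
  }, numeric(1))
}

#' Normalized perfusion-weighted drug concentration field
#'
#' Evaluates the normalized concentration of one drug at time `t`: the sum
#' over delivered doses of an exponentially decaying bolus, weighted
#' voxelwise by the static perfusion map. Non-negative everywhere and zero
#' wherever perfusion vanishes.
#'
#' @param drug A [drug_spec()].
#' @param p A [scalar_field()] perfusion map with values in `[0, 1]`.
#' @param t Non-negative time (days).
#' @return A [scalar_field()] of normalized concentration.
#' @examples
#' g <- make_grid(c(4, 4, 4), 1)
#' p <- scalar_field(g, 1)
#' d <- drug_spec("dox", 0, dmax_norm = 2, decay = 0.45)
#' max(concentration(d, p, 0)$values) # 2 at the delivery instant
#' @export
concentration <- function(drug, p, t) {
  stopifnot(inherits(p, "scalar_field"), length(t) == 1)
  scalar_field(p$grid, dose_factor(drug, t) * p$values)
}
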