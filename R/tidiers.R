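#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a sensitivity-analysis result
#'
#' One row per (time, quantity of interest, parameter) with the
#' total-effects index; end-of-treatment rows carry the bootstrap interval
#' and the influence label.
#'
#' @param x An `sa_result`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `qoi`, `parameter`, `ST`,
#'   `ci_lo`, `ci_hi`, `influential`.
#' @export
tidy.sa_result <- function(x, ...) {
  n_t <- length(x$times)
  qois <- c("VT", "NT")
  params <- x$space$name
  out <- tidyr::expand_grid(
    time = x$times, qoi = qois, parameter = params
  )
  out$ST <- mapply(function(tt, q, p) {
    x$ST[match(tt, x$times), q, p]
  }, out$time, out$qoi, out$parameter)
  at_end <- out$time == x$times[n_t]
  out$ci_lo <- NA_real_
  out$ci_hi <- NA_real_
  out$ci_lo[at_end] <- mapply(function(q, p) x$ci["lo", q, p],
                              out$qoi[at_end], out$parameter[at_end])
  out$ci_hi[at_end] <- mapply(function(q, p) x$ci["hi", q, p],
                              out$qoi[at_end], out$parameter[at_end])
  out$influential <- mapply(function(q, p) x$influential[q, p],
                            out$qoi, out$parameter)
  out
}

#' Summarize a sensitivity-analysis result
#'
#' @param x An `sa_result`.
#' @param ... Unused.
#' @return A one-row tibble with the campaign size and the number of
#'   influential parameters per quantity of interest.
#' @export
glance.sa_result <- function(x, ...) {
  tibble::tibble(
    regimen = x$regimen_kind,
    scenario = x$scenario_label,
    n_s = x$n_s,
    n_runs = x$n_s * (nrow(x$space) + 2),
    eps_s = x$eps_s,
    n_influential_VT = sum(x$influential["VT", ]),
    n_influential_NT = sum(x$influential["NT", ]),
    n_influential = sum(colSums(x$influential) > 0)
  )
}

#' Tidy a trajectory's quantity-of-interest series
#'
#' @param x An `nac_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `VT`, `NT`.
#' @export
tidy.nac_trajectory <- function(x, ...) {
  x$qoi
}

#' Summarize an original-versus-reduced-model comparison
#'
#' Pearson and concordance correlations between the paired end-of-treatment
#' outcomes of the original and reduced models.
#'
#' @param x A `reduced_comparison` tibble.
#' @param ... Unused.
#' @return A tibble with one row per quantity of interest and columns
#'   `qoi`, `pcc`, `ccc`, `n`.
#' @export
glance.reduced_comparison <- function(x, ...) {
  pairs <- list(VT = c("VT_orig", "VT_red"), NT = c("NT_orig", "NT_red"))
  if ("MRD_orig" %in% names(x)) {
    pairs$MRD <- c("MRD_orig", "MRD_red")
  }
  purrr::map_dfr(names(pairs), function(q) {
    a <- x[[pairs[[q]][1]]]
    b <- x[[pairs[[q]][2]]]
    tibble::tibble(qoi = q, pcc = pcc(a, b), ccc = ccc(a, b), n = length(a))
  })
}
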