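#' Plot a trajectory's quantities of interest
#'
#' Tumor volume (converted to cc) and total cell count over the course of
#' treatment, on free y scales.
#'
#' @param object An `nac_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nac_trajectory <- function(object, ...) {
  df <- dplyr::mutate(object$qoi, VT = .data$VT / 1000)
  df <- tidyr::pivot_longer(df, c("VT", "NT"), names_to = "qoi",
                            values_to = "value")
  df$qoi <- factor(df$qoi, levels = c("VT", "NT"),
                   labels = c("tumor volume (cc)", "total cells"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~qoi, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL,
                  title = sprintf("%s, %s scenario", object$regimen_kind,
                                  object$scenario_label)) +
    ggplot2::theme_minimal()
}

#' Plot time-resolved total-effects indices
#'
#' One panel per quantity of interest; parameters flagged influential at
#' the end of treatment are drawn with solid lines, the rest dashed, with
#' the influence threshold as a horizontal reference.
#'
#' @param object An `sa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sa_result <- function(object, ...) {
  df <- tidy(object)
  df$flag <- ifelse(df$influential, "influential", "non-influential")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ST,
                                   colour = .data$parameter,
                                   linetype = .data$flag,
                                   group = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$eps_s, linetype = "dotted") +
    ggplot2::facet_wrap(~qoi) +
    ggplot2::labs(x = "time (days)", y = "total-effects index",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Unity plot of original versus reduced model outcomes
#'
#' @param object A `reduced_comparison` tibble.
#' @param qoi Which outcome to plot: `"VT"`, `"NT"` or `"MRD"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduced_comparison <- function(object, qoi = c("VT", "NT", "MRD"),
                                        ...) {
  qoi <- match.arg(qoi)
  xs <- paste0(qoi, "_orig")
  ys <- paste0(qoi, "_red")
  if (!xs %in% names(object)) {
    stop("outcome ", qoi, " not present in the comparison", call. = FALSE)
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xs]], y = .data[[ys]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste(qoi, "(original model)"),
                  y = paste(qoi, "(reduced model)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
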