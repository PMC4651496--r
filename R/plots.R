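#' Plot per-residue chemical shift perturbations
#'
#' Bar plot of CSP against residue number with the significance
#' threshold as a dashed line; significant residues are highlighted and
#' disappeared residues marked along the axis, mirroring the standard
#' CSP-index figure of an NMR titration study.
#'
#' @param csps Tibble of CSP records from [compute_csp()].
#' @param threshold Significance threshold, ppm (drawn and used for
#'   colouring; default 0.028).
#' @return A ggplot object.
#' @export
plot_csp <- function(csps, threshold = 0.028) {
  measured <- dplyr::filter(csps, .data$status == "measured") |>
    dplyr::mutate(significant = .data$csp > threshold)
  gone <- dplyr::filter(csps, .data$status == "disappeared")
  p <- ggplot2::ggplot(measured, ggplot2::aes(x = .data$residue, y = .data$csp)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = sprintf("CSP > %g ppm", threshold)) +
    ggplot2::labs(x = "residue", y = "CSP (ppm)") +
    ggplot2::theme_minimal()
  if (nrow(gone) > 0L)
    p <- p + ggplot2::geom_point(data = gone,
                                 ggplot2::aes(x = .data$residue, y = 0),
                                 shape = 4, colour = "orange", size = 2)
  p
}

#' Plot contact frequencies from a docking ensemble
#'
#' @param profile A `contact_profile` from [contact_frequency()].
#' @param epitope Optional [epitope_set()] whose residues are marked.
#' @param min_frequency Optional horizontal reference line (e.g. the
#'   docking-epitope threshold).
#' @return A ggplot object.
#' @export
plot_contact_frequency <- function(profile, epitope = NULL,
                                   min_frequency = NULL) {
  df <- as_tibble(profile)
  df$planted <- if (is.null(epitope)) FALSE else
    df$residue %in% (if (inherits(epitope, "epitope_set")) epitope$residues
                     else as.integer(epitope))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$frequency)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$planted), width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "navy"),
                               guide = if (is.null(epitope)) "none" else "legend",
                               name = "epitope") +
    ggplot2::labs(x = "antigen residue", y = "contact frequency") +
    ggplot2::theme_minimal()
  if (!is.null(min_frequency))
    p <- p + ggplot2::geom_hline(yintercept = min_frequency, linetype = "dashed")
  p
}

#' @export
autoplot.contact_profile <- function(object, ...) {
  plot_contact_frequency(object, ...)
}

#' Plot R2/R1 relaxation ratios by state
#'
#' @param rates Tibble from the relaxation stage: columns `residue`,
#'   `ratio_R2_over_R1` and `state` (e.g. free vs complex).
#' @return A ggplot object.
#' @export
plot_relaxation <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$residue,
                                      y = .data$ratio_R2_over_R1,
                                      colour = .data$state)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "residue", y = "R2/R1") +
    ggplot2::theme_minimal()
}
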