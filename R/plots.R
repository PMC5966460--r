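#' Volcano plot of proteome results
#'
#' Mean paired log2 fold change against -log10 p-value, faceted by
#' comparison, significant proteins (q below the stored threshold)
#' highlighted.
#'
#' @param object A `proteome_results` tibble from [paired_differential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proteome_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate,
                                       y = -log10(.data$p_value),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (treatment / reference)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Volcano plot of microbiome comparison results
#'
#' Posterior mean log10 ratio against -log10 q-value per taxon, faceted by
#' comparison; the horizontal line marks the q threshold.
#'
#' @param object A `study_results` from [run_all_comparisons()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_results <- function(object, ...) {
  ggplot2::ggplot(object$taxa, ggplot2::aes(x = .data$effect,
                                            y = -log10(.data$q_value),
                                            colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(object$q_threshold),
                        colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "forestgreen")) +
    ggplot2::labs(x = "log10 ratio (treatment / control)", y = "-log10 q",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Calibration plot of the measurement-error model
#'
#' Empirical per-taxon log10-abundance standard deviations against their
#' median log10 relative abundance, with the fitted (floored, monotone)
#' law.
#'
#' @param object A `measurement_error_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.measurement_error_model <- function(object, ...) {
  d <- tidy(object)
  grid <- tibble(m = seq(min(d$m), max(d$m), length.out = 200))
  grid$sigma <- predict(object, grid$m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data$sigma_emp)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$sigma),
                       colour = "firebrick") +
    ggplot2::labs(x = "median log10 relative abundance",
                  y = "sd of log10 relative abundance") +
    ggplot2::theme_minimal()
}

#' Trace plot of a chain set
#'
#' @param object A `chain_set`.
#' @param parameters Optional character vector restricting the panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_set <- function(object, parameters = NULL, ...) {
  pnames <- dimnames(object)[[3]]
  parameters <- parameters %||% head(pnames, 6)
  d <- list_rbind(lapply(parameters, function(p) {
    mat <- param_matrix(object, p)
    tibble(
      parameter = p,
      iteration = rep(seq_len(nrow(mat)), times = ncol(mat)),
      chain = factor(rep(seq_len(ncol(mat)), each = nrow(mat))),
      value = as.vector(mat)
    )
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = "draw") +
    ggplot2::theme_minimal()
}

#' Total-abundance outlier report plot
#'
#' @param object An `outlier_report` from [flag_outlier_samples()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outlier_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id, y = .data$total,
                                       colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower[1]),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper[1]),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "total normalized abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
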