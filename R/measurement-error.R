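#' Calibrate the measurement-error model from positive controls
#'
#' Replicate sequencing runs of one fixed specimen reveal how the technical
#' variance of a taxon's log10 relative abundance grows as the taxon gets
#' rarer. Per taxon detected in every replicate, the median `m` and variance
#' `v` of its log10 relative abundance are computed across replicates;
#' `log10(v)` is then regressed linearly on `m`. The fitted mapping
#' `sigma(m) = sqrt(10^(a + b m))` is floored at `sigma_floor` and
#' monotonized (a positive slope, which would make abundant taxa noisier,
#' is clamped to zero).
#'
#' @param x A `positive_controls` object from [gen_positive_controls()], or
#'   a long count tibble (`taxon_id`, `sample_id`, `count`), each sample one
#'   replicate.
#' @param meta Sample metadata with `sample_id`, `total_reads`; unused when
#'   `x` is a `positive_controls` object.
#' @param sigma_floor Lower bound on the predicted sd. Default 1e-3.
#' @return Object of class `measurement_error_model` with the fitted
#'   coefficients, the per-taxon calibration table, and a [predict()] method
#'   mapping median log10 relative abundance to a standard deviation.
#' @examples
#' pc <- gen_positive_controls(study_config(n_taxa = 30, seed = 1))
#' mem <- fit_measurement_error_model(pc)
#' predict(mem, m = c(-1, -4))
#' @export
fit_measurement_error_model <- function(x, meta = NULL, sigma_floor = 1e-3) {
  if (inherits(x, "positive_controls")) {
    counts <- x$counts
    meta <- x$meta
  } else {
    counts <- x
    if (is.null(meta)) abort("`meta` with total_reads is required")
  }
  check_long(counts, "count")
  n_reps <- dplyr::n_distinct(counts$sample_id)
  if (n_reps < 3) abort("need at least 3 positive-control replicates")

  calib <- counts |>
    inner_join(select(meta, "sample_id", "total_reads"), by = "sample_id") |>
    group_by(.data$taxon_id) |>
    filter(all(.data$count > 0)) |>
    summarise(m = median(log10(.data$count / .data$total_reads)),
              v = var(log10(.data$count / .data$total_reads)),
              .groups = "drop")
  if (nrow(calib) < 5) {
    abort("fewer than 5 taxa detected in every replicate; cannot calibrate")
  }

  fit_pts <- filter(calib, .data$v > 0)
  if (nrow(fit_pts) < 2 || sd(fit_pts$m) == 0) {
    # degenerate replicates: no usable variance signal, fall back to floor
    coefs <- c(intercept = log10(sigma_floor^2), slope = 0)
    r2 <- NA_real_
  } else {
    fit <- lm(log10(v) ~ m, data = fit_pts)
    coefs <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
    r2 <- summary(fit)$r.squared
    if (coefs["slope"] > 0) {
      # enforce non-increasing sigma(m): refuse an inverted law
      coefs["intercept"] <- mean(log10(fit_pts$v))
      coefs["slope"] <- 0
    }
  }
  structure(list(
    intercept = unname(coefs["intercept"]),
    slope = unname(coefs["slope"]),
    sigma_floor = sigma_floor,
    range = if (nrow(fit_pts) > 0) range(fit_pts$m) else c(NA_real_, NA_real_),
    calibration = calib,
    r_squared = r2,
    n_replicates = n_reps
  ), class = "measurement_error_model")
}

#' @rdname fit_measurement_error_model
#' @param object A `measurement_error_model`.
#' @param m Median log10 relative abundance(s) at which to evaluate.
#' @param ... Unused.
#' @return `predict()`: numeric vector of standard deviations (>= the
#'   floor, non-increasing in `m`).
#' @export
predict.measurement_error_model <- function(object, m, ...) {
  pmax(object$sigma_floor, sqrt(10^(object$intercept + object$slope * m)))
}

#' @export
print.measurement_error_model <- function(x, ...) {
  cat(sprintf(
    "<measurement_error_model: sigma(m) = max(%.3g, sqrt(10^(%.3f %+.3f m))), %d taxa, %d replicates>\n",
    x$sigma_floor, x$intercept, x$slope, nrow(x$calibration), x$n_replicates))
  invisible(x)
}

#' @rdname fit_measurement_error_model
#' @export
tidy.measurement_error_model <- function(x, ...) {
  mutate(x$calibration, sigma_emp = sqrt(.data$v),
         sigma_fit = predict(x, .data$m))
}

#' @rdname fit_measurement_error_model
#' @export
glance.measurement_error_model <- function(x, ...) {
  tibble(intercept = x$intercept, slope = x$slope, r_squared = x$r_squared,
         sigma_floor = x$sigma_floor, n_taxa = nrow(x$calibration),
         n_replicates = x$n_replicates)
}
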