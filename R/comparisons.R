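#' Run every microbiome comparison of the crossover design
#'
#' For each registry comparison: builds the per-subject pairs, applies
#' [filter_taxa()], fits the binomial logistic-normal paired model
#' ([fit_abundance_model()]) to every retained taxon, adjusts the posterior
#' tail p-values with Benjamini-Hochberg *within* the comparison
#' (significant at `q_threshold`, default 1% FDR), and fits the paired
#' normal-Laplace Shannon-diversity model ([fit_diversity_model()]) on the
#' same pairs. Comparisons with fewer than 3 complete pairs are skipped
#' with a warning.
#'
#' @param counts Long count tibble (`taxon_id`, `sample_id`, `count`).
#' @param meta Sample metadata (`sample_id`, `subject_id`, `arm`,
#'   `formulation`, `timepoint`, `total_reads`).
#' @param error_model A [fit_measurement_error_model()] object.
#' @param settings An [mcmc_settings()].
#' @param comparisons Registry tibble; default [microbiome_comparisons()].
#' @param freq,prevalence,min_subjects Passed to [filter_taxa()].
#' @param q_threshold Significance threshold on taxon q-values. Default
#'   0.01.
#' @param seed Integer seed; per-taxon fits receive derived seeds.
#' @param engine Passed to the model fits.
#' @return Object of class `study_results`: list with
#'   \describe{
#'     \item{taxa}{volcano-ready tibble: `comparison`, `taxon_id`, `effect`
#'       (posterior mean log10 ratio), `conf.low`, `conf.high`, `p_value`,
#'       `q_value`, `significant`, `psrf`, `converged`, `n`, and the median
#'       observed proportions in treatment, control and at 7 d}
#'     \item{diversity}{per-comparison Shannon-diversity effects}
#'   }
#' @export
run_all_comparisons <- function(counts, meta, error_model,
                                settings = mcmc_settings(),
                                comparisons = microbiome_comparisons(),
                                freq = 1e-5, prevalence = 0.25,
                                min_subjects = 4, q_threshold = 0.01,
                                seed = 1L, engine = "jags") {
  check_long(counts, "count")
  totals <- select(meta, "sample_id", "total_reads")

  taxa_rows <- list()
  div_rows <- list()
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    pairs <- build_pairs(meta, cmp)
    if (nrow(pairs) < 3) {
      warn(sprintf("comparison '%s' skipped: only %d complete pair(s)",
                   cmp$label, nrow(pairs)))
      next
    }
    filtered <- tryCatch(
      filter_taxa(counts, meta, pairs, freq = freq, prevalence = prevalence,
                  min_subjects = min_subjects),
      error = function(e) NULL
    )
    if (is.null(filtered)) {
      warn(sprintf("comparison '%s' skipped: all taxa filtered", cmp$label))
      next
    }
    taxa <- sort(unique(filtered$taxon_id))

    pair_counts <- make_pair_counts(filtered, totals, pairs)
    seven_day <- seven_day_proportions(counts, meta, cmp, pairs)

    fits <- lapply(seq_along(taxa), function(j) {
      d <- filter(pair_counts, .data$taxon_id == taxa[j])
      fit <- fit_abundance_model(
        select(d, "yT", "nT", "yC", "nC"), error_model,
        settings = settings, seed = seed + 1009L * i + j, engine = engine
      )
      if (is.null(fit)) return(NULL)
      g <- glance(fit)
      tibble(
        taxon_id = taxa[j],
        effect = g$estimate, conf.low = g$conf.low, conf.high = g$conf.high,
        p_value = g$p_value, psrf = g$psrf, converged = g$converged,
        n = g$n_pairs,
        median_prop_treatment = median(d$yT / d$nT),
        median_prop_control = median(d$yC / d$nC)
      )
    })
    tab <- list_rbind(fits[!vapply(fits, is.null, logical(1))])
    if (nrow(tab) > 0) {
      tab <- tab |>
        mutate(q_value = bh_adjust(.data$p_value),
               significant = .data$q_value < q_threshold,
               comparison = cmp$label) |>
        left_join(seven_day, by = "taxon_id")
      taxa_rows[[length(taxa_rows) + 1]] <- tab
    }

    div_rows[[length(div_rows) + 1]] <-
      diversity_for_comparison(filtered, pairs, cmp$label, settings,
                               seed + 1009L * i + 999L, engine)
  }

  taxa_tab <- if (length(taxa_rows)) {
    list_rbind(taxa_rows) |>
      select("comparison", "taxon_id", "effect", "conf.low", "conf.high",
             "p_value", "q_value", "significant", "psrf", "converged", "n",
             "median_prop_treatment", "median_prop_control", "median_prop_7d")
  } else {
    tibble()
  }
  structure(list(
    taxa = taxa_tab,
    diversity = list_rbind(div_rows),
    comparisons = comparisons,
    q_threshold = q_threshold,
    settings = settings
  ), class = "study_results")
}

make_pair_counts <- function(filtered, totals, pairs) {
  dat <- inner_join(filtered, totals, by = "sample_id")
  treat <- dat |>
    inner_join(tibble(sample_id = pairs$treat_sample,
                      subject_id = pairs$subject_id), by = "sample_id") |>
    select("taxon_id", "subject_id", yT = "count", nT = "total_reads")
  ctrl <- dat |>
    inner_join(tibble(sample_id = pairs$control_sample,
                      subject_id = pairs$subject_id), by = "sample_id") |>
    select("taxon_id", "subject_id", yC = "count", nC = "total_reads")
  inner_join(treat, ctrl, by = c("taxon_id", "subject_id"))
}

seven_day_proportions <- function(counts, meta, cmp, pairs) {
  m7 <- meta |>
    filter(.data$arm == cmp$arm, .data$formulation == cmp$formulation,
           .data$timepoint == "7d", .data$subject_id %in% pairs$subject_id)
  if (nrow(m7) == 0) {
    return(tibble(taxon_id = character(0), median_prop_7d = numeric(0)))
  }
  counts |>
    inner_join(select(m7, "sample_id", "total_reads"), by = "sample_id") |>
    group_by(.data$taxon_id) |>
    summarise(median_prop_7d = median(.data$count / .data$total_reads),
              .groups = "drop")
}

diversity_for_comparison <- function(filtered, pairs, label, settings, seed,
                                     engine) {
  sh <- sample_shannon(filtered)
  n_taxa <- sh$n_taxa[1]
  y <- setNames(logit_scaled_shannon(sh$shannon, n_taxa), sh$sample_id)
  d <- tibble(yT = unname(y[pairs$treat_sample]),
              yC = unname(y[pairs$control_sample]))
  fit <- fit_diversity_model(d, settings = settings, seed = seed,
                             engine = engine)
  mutate(glance(fit), comparison = label, .before = 1)
}

#' @rdname run_all_comparisons
#' @param x A `study_results` object.
#' @param ... Unused.
#' @export
tidy.study_results <- function(x, ...) x$taxa

#' @rdname run_all_comparisons
#' @export
glance.study_results <- function(x, ...) {
  x$taxa |>
    group_by(.data$comparison) |>
    summarise(n_taxa = n(), n_significant = sum(.data$significant),
              max_psrf = max(.data$psrf), .groups = "drop")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results: %d comparisons, %d taxon fits, %d significant at q < %g>\n",
              dplyr::n_distinct(x$taxa$comparison), nrow(x$taxa),
              sum(x$taxa$significant), x$q_threshold))
  print(glance(x), ...)
  invisible(x)
}
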