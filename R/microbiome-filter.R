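#' Build per-subject treatment/control sample pairs
#'
#' Resolves one row of the comparison registry into per-subject
#' (treatment sample, control sample) pairs. For `vs_baseline` comparisons
#' the control is the subject's matched pre-gel (t0) swab from the same arm
#' and formulation; for `grft_vs_placebo` it is the placebo swab at the
#' matched time point within the formulation.
#'
#' @param meta Sample metadata (`sample_id`, `subject_id`, `arm`,
#'   `formulation`, `timepoint`).
#' @param comparison One-row tibble from [microbiome_comparisons()] (or
#'   [proteome_comparisons()]).
#' @return Tibble of class `paired_design`: `subject_id`, `treat_sample`,
#'   `control_sample`, with the comparison label as attribute `"label"`.
#' @export
build_pairs <- function(meta, comparison) {
  stopifnot(nrow(comparison) == 1)
  treat <- meta |>
    filter(.data$arm == comparison$arm,
           .data$formulation == comparison$formulation,
           .data$timepoint == comparison$timepoint) |>
    select("subject_id", treat_sample = "sample_id")
  control <- if (comparison$type == "vs_baseline") {
    meta |>
      filter(.data$arm == comparison$arm,
             .data$formulation == comparison$formulation,
             .data$timepoint == "t0") |>
      select("subject_id", control_sample = "sample_id")
  } else {
    meta |>
      filter(.data$arm == "placebo",
             .data$formulation == comparison$formulation,
             .data$timepoint == comparison$timepoint) |>
      select("subject_id", control_sample = "sample_id")
  }
  out <- inner_join(treat, control, by = "subject_id") |>
    filter(.data$treat_sample != .data$control_sample)
  attr(out, "label") <- comparison$label
  class(out) <- c("paired_design", class(out))
  out
}

#' Filter taxa before modelling
#'
#' Retains taxa that pass all of: study-wide mean relative abundance above
#' `freq`; detected (non-zero count) in at least a `prevalence` fraction of
#' all samples; and, when a comparison's pairs are supplied, detected in at
#' least `min_subjects` of the comparison's subjects (in either member of
#' the subject's pair). Relative abundances use the recorded per-sample
#' totals in `meta`, so the filter is idempotent.
#'
#' @param counts Long count tibble (`taxon_id`, `sample_id`, `count`).
#' @param meta Sample metadata with `sample_id` and `total_reads`.
#' @param pairs Optional [build_pairs()] design for the per-comparison rule.
#' @param freq Study-wide mean relative-abundance floor. Default 1e-5.
#' @param prevalence Minimum detection fraction across samples. Default 0.25.
#' @param min_subjects Minimum subjects with detection within the
#'   comparison. Default 4.
#' @return Filtered `counts`; dropped taxa (and the rule that removed them)
#'   in attribute `"dropped"`.
#' @export
filter_taxa <- function(counts, meta, pairs = NULL, freq = 1e-5,
                        prevalence = 0.25, min_subjects = 4) {
  check_long(counts, "count")
  if (nrow(counts) == 0) abort("empty count table")
  dat <- inner_join(counts, select(meta, "sample_id", "total_reads"),
                    by = "sample_id")
  study <- dat |>
    group_by(.data$taxon_id) |>
    summarise(mean_rel = mean(.data$count / .data$total_reads),
              detect_frac = mean(.data$count > 0), .groups = "drop") |>
    mutate(pass_freq = .data$mean_rel > freq,
           pass_prev = .data$detect_frac >= prevalence)
  if (!is.null(pairs)) {
    cmp_samples <- tibble(
      subject_id = rep(pairs$subject_id, 2),
      sample_id = c(pairs$treat_sample, pairs$control_sample)
    )
    subj_detect <- counts |>
      inner_join(cmp_samples, by = "sample_id",
                 relationship = "many-to-many") |>
      group_by(.data$taxon_id, .data$subject_id) |>
      summarise(present = any(.data$count > 0), .groups = "drop") |>
      group_by(.data$taxon_id) |>
      summarise(n_subjects = sum(.data$present), .groups = "drop")
    study <- left_join(study, subj_detect, by = "taxon_id") |>
      mutate(pass_subj = dplyr::coalesce(.data$n_subjects, 0L) >= min_subjects)
  } else {
    study$pass_subj <- TRUE
  }
  study <- mutate(study,
                  keep = .data$pass_freq & .data$pass_prev & .data$pass_subj)
  if (!any(study$keep)) abort("all taxa removed by the filter")
  dropped <- study |>
    filter(!.data$keep) |>
    mutate(reason = paste0(
      ifelse(!.data$pass_freq, "frequency;", ""),
      ifelse(!.data$pass_prev, "prevalence;", ""),
      ifelse(!.data$pass_subj, "min_subjects;", ""))) |>
    select("taxon_id", "mean_rel", "detect_frac", "reason")
  if (nrow(dropped) > 0) {
    inform(sprintf("taxa filter removed %d/%d taxa", nrow(dropped),
                   nrow(study)))
  }
  out <- filter(counts, .data$taxon_id %in% study$taxon_id[study$keep])
  attr(out, "dropped") <- dropped
  out
}

#' Shannon diversity of a composition
#'
#' `H = -sum(p * ln p)` over a vector of proportions (natural log;
#' `0 * log 0` taken as 0).
#'
#' @param proportions Non-negative vector summing to 1 (tolerance 1e-9).
#' @return Single non-negative number.
#' @examples
#' shannon(rep(1 / 10, 10)) # = ln 10
#' @export
shannon <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("proportions must sum to 1 (tolerance 1e-9)")
  }
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of a count table
#'
#' @param counts Long count tibble.
#' @return Tibble `sample_id`, `shannon`, plus `n_taxa` (taxa in the table,
#'   the scaling constant for [logit_scaled_shannon()]).
#' @export
sample_shannon <- function(counts) {
  check_long(counts, "count")
  n_taxa <- dplyr::n_distinct(counts$taxon_id)
  counts |>
    group_by(.data$sample_id) |>
    summarise(shannon = {
      tot <- sum(.data$count)
      if (tot == 0) 0 else shannon(.data$count / tot)
    }, .groups = "drop") |>
    mutate(n_taxa = n_taxa)
}

#' Logit transform of scaled Shannon diversity
#'
#' Shannon diversity over `n_taxa` categories is bounded by `ln(n_taxa)`;
#' dividing by that bound (Pielou-style evenness scaling) maps it to (0, 1),
#' and the logit of the clamped ratio gives an unbounded, approximately
#' normal quantity suitable for the Gaussian diversity model.
#' `y = logit(clamp(H / ln(n_taxa), eps, 1 - eps))` with `eps = 1e-6`.
#'
#' @param H Shannon diversity value(s), in `[0, ln(n_taxa)]`.
#' @param n_taxa Number of taxa the diversity was computed over (>= 2).
#' @param eps Clamp width. Default 1e-6.
#' @return Transformed value(s); [inv_logit_scaled_shannon()] inverts on the
#'   unclamped range.
#' @examples
#' logit_scaled_shannon(log(10) / 2, n_taxa = 10) # midpoint -> 0
#' @export
logit_scaled_shannon <- function(H, n_taxa, eps = 1e-6) {
  if (n_taxa < 2) abort("`n_taxa` must be >= 2")
  hmax <- log(n_taxa)
  if (any(H > hmax + 1e-8) || any(H < -1e-8)) {
    abort(sprintf("Shannon value outside [0, ln(%d) = %.4f]", n_taxa, hmax))
  }
  ratio <- pmin(pmax(H / hmax, eps), 1 - eps)
  qlogis(ratio)
}

#' @rdname logit_scaled_shannon
#' @param y Transformed value(s).
#' @export
inv_logit_scaled_shannon <- function(y, n_taxa) {
  if (n_taxa < 2) abort("`n_taxa` must be >= 2")
  plogis(y) * log(n_taxa)
}
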