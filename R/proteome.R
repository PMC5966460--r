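#' Total-signal normalization
#'
#' Scales every sample's intensities by a single factor so that all samples
#' share the same total signal (the across-sample mean of the raw totals).
#' Within-sample relative proportions are unchanged.
#'
#' @param data Long tibble with columns `protein_id`, `sample_id`,
#'   `intensity`.
#' @return `data` with rescaled `intensity`.
#' @examples
#' d <- tibble::tibble(protein_id = "P1", sample_id = c("a", "b"),
#'                     intensity = c(100, 200))
#' normalize_total_signal(d)
#' @export
normalize_total_signal <- function(data) {
  check_long(data, "intensity")
  totals <- data |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$intensity), .groups = "drop")
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero)) {
    abort(sprintf("sample(s) with non-positive total intensity: %s",
                  toString(zero)))
  }
  target <- mean(totals$total)
  data |>
    left_join(totals, by = "sample_id") |>
    mutate(intensity = .data$intensity * target / .data$total) |>
    select(-"total")
}

#' Technical-replicate coefficient-of-variation filter
#'
#' Computes each protein's coefficient of variation (sd/mean) across the
#' technical replicates of the pooled reference and retains proteins with
#' CV strictly below `cv_threshold` (default 25%). Dropped proteins are
#' reported via a message and the `"dropped"` attribute.
#'
#' @param data Long intensity tibble (`protein_id`, `sample_id`,
#'   `intensity`).
#' @param meta Sample metadata with `sample_id` and `is_tech_replicate`.
#' @param cv_threshold Retention threshold on the CV. Default 0.25.
#' @return Filtered `data`; attribute `"dropped"` holds a tibble of removed
#'   proteins and their replicate CVs.
#' @export
filter_by_replicate_cv <- function(data, meta, cv_threshold = 0.25) {
  check_long(data, "intensity")
  reps <- meta$sample_id[meta$is_tech_replicate]
  if (length(reps) < 2) {
    abort("need at least 2 technical-replicate samples to compute CVs")
  }
  cvs <- data |>
    filter(.data$sample_id %in% reps) |>
    group_by(.data$protein_id) |>
    summarise(cv = sd(.data$intensity) / mean(.data$intensity),
              .groups = "drop")
  dropped <- filter(cvs, !(.data$cv < cv_threshold))
  if (nrow(dropped) > 0) {
    inform(sprintf("replicate-CV filter removed %d/%d proteins (CV >= %g)",
                   nrow(dropped), nrow(cvs), cv_threshold))
  }
  out <- filter(data, !.data$protein_id %in% dropped$protein_id)
  attr(out, "dropped") <- dropped
  out
}

#' Median-profile normalization
#'
#' For each sample, fits the sample's intensities against the across-sample
#' median intensity profile by no-intercept linear regression
#' (`intensity ~ 0 + profile`) and divides the sample by the fitted slope,
#' so the correction is a pure per-sample rescaling and the refitted slope
#' is exactly 1. A sample that is a constant multiple of the median profile
#' is undone exactly (e.g. 2x the profile is scaled by 1/2).
#'
#' @param data Long intensity tibble; all intensities must be positive.
#' @return `data` with rescaled `intensity`.
#' @export
median_normalize <- function(data) {
  check_long(data, "intensity")
  if (dplyr::n_distinct(data$protein_id) < 2) {
    abort("median normalization needs more than one protein")
  }
  if (any(data$intensity <= 0)) {
    abort("median normalization needs strictly positive intensities")
  }
  profile <- data |>
    group_by(.data$protein_id) |>
    summarise(m = median(.data$intensity), .groups = "drop")
  if (sd(profile$m) == 0) abort("constant median profile: cannot normalize")
  slopes <- data |>
    left_join(profile, by = "protein_id") |>
    group_by(.data$sample_id) |>
    summarise(b = sum(.data$m * .data$intensity) / sum(.data$m^2),
              .groups = "drop")
  if (any(slopes$b <= 0)) abort("non-positive fitted slope; cannot rescale")
  data |>
    left_join(slopes, by = "sample_id") |>
    mutate(intensity = .data$intensity / .data$b) |>
    select(-"b")
}

#' Combined proteome normalization
#'
#' The pipeline's normalization stage: [normalize_total_signal()] followed
#' by [median_normalize()], in that order. After this, every sample's
#' no-intercept regression slope against the median profile is exactly 1,
#' and re-applying [median_normalize()] changes the matrix only at
#' numerical noise. (Equal linear totals and unit median-profile slopes are
#' competing constraints on one scale factor per sample, so the median fit
#' — the later, finer correction — is the one left exactly satisfied.)
#'
#' @param data Long intensity tibble.
#' @return Normalized `data`.
#' @export
normalize_proteome <- function(data) {
  median_normalize(normalize_total_signal(data))
}

#' Flag outlier samples by total abundance
#'
#' Reports samples whose total normalized abundance lies outside
#' `median +/- k * IQR` (default fence, following the per-sample rule of the
#' study protocol) or outside the Tukey fences
#' `[Q1 - k * IQR, Q3 + k * IQR]` (`fence = "quartile"`). Outliers are
#' reported, never removed: longitudinal designs keep all samples.
#'
#' @param data Long intensity tibble.
#' @param k Fence multiplier. Default 1.5.
#' @param fence `"median"` (default) or `"quartile"`.
#' @return Tibble of class `outlier_report`: `sample_id`, `total`, `lower`,
#'   `upper`, `flagged`.
#' @export
flag_outlier_samples <- function(data, k = 1.5, fence = c("median", "quartile")) {
  check_long(data, "intensity")
  fence <- match.arg(fence)
  totals <- data |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$intensity), .groups = "drop")
  if (nrow(totals) < 4) abort("outlier flagging needs at least 4 samples")
  q <- quantile(totals$total, c(0.25, 0.5, 0.75), type = 7)
  iqr <- q[[3]] - q[[1]]
  bounds <- if (fence == "median") {
    c(q[[2]] - k * iqr, q[[2]] + k * iqr)
  } else {
    c(q[[1]] - k * iqr, q[[3]] + k * iqr)
  }
  out <- totals |>
    mutate(lower = bounds[1], upper = bounds[2],
           flagged = .data$total < bounds[1] | .data$total > bounds[2])
  class(out) <- c("outlier_report", class(out))
  out
}

#' Per-subject baseline profile
#'
#' Arithmetic mean of each protein's intensity over a subject's baseline
#' samples.
#'
#' @param data Long intensity tibble.
#' @param meta Sample metadata (`sample_id`, `subject_id`, `timepoint`).
#' @return Tibble `subject_id`, `protein_id`, `baseline`.
#' @export
baseline_average <- function(data, meta) {
  check_long(data, "intensity")
  subjects <- unique(meta$subject_id[!is.na(meta$subject_id)])
  base_meta <- filter(meta, .data$timepoint %in% "baseline")
  missing <- setdiff(subjects, unique(base_meta$subject_id))
  if (length(missing)) {
    abort(sprintf("subject(s) with no baseline sample: %s", toString(missing)))
  }
  data |>
    inner_join(select(base_meta, "sample_id", "subject_id"), by = "sample_id") |>
    group_by(.data$subject_id, .data$protein_id) |>
    summarise(baseline = mean(.data$intensity), .groups = "drop")
}

#' Paired differential expression
#'
#' For every comparison in the registry, forms per-subject log2 ratios of
#' treatment over reference (the averaged baseline for `vs_baseline`
#' comparisons; the matched placebo time point for `grft_vs_placebo`),
#' applies a two-tailed paired t test across subjects per protein, and
#' adjusts p-values with Benjamini-Hochberg within the comparison. Proteins
#' with a zero or missing intensity in any needed ratio are excluded from
#' that comparison with a warning (no imputation in a small paired design).
#' Proteins whose ratios are identically zero are reported with p = 1.
#'
#' @param data Long intensity tibble (normalized).
#' @param meta Sample metadata.
#' @param comparisons Registry tibble, see [proteome_comparisons()].
#' @param q_threshold Significance threshold on the q-value. Default 0.05
#'   (5% FDR).
#' @return Tibble of class `proteome_results`: `comparison`, `protein_id`,
#'   `estimate` (mean log2 fold change), `statistic`, `df`, `p_value`,
#'   `q_value`, `significant`, `n`.
#' @export
paired_differential <- function(data, meta, comparisons = proteome_comparisons(),
                                q_threshold = 0.05) {
  check_long(data, "intensity")
  baselines <- if (any(comparisons$type == "vs_baseline")) {
    baseline_average(data, meta)
  }
  dat <- inner_join(data,
                    select(meta, "sample_id", "subject_id", "arm",
                           "formulation", "timepoint"),
                    by = "sample_id")

  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    treat <- dat |>
      filter(.data$arm == cmp$arm, .data$formulation == cmp$formulation,
             .data$timepoint == cmp$timepoint) |>
      select("protein_id", "subject_id", treat = "intensity")
    ref <- if (cmp$type == "vs_baseline") {
      rename(baselines, ref = "baseline")
    } else {
      dat |>
        filter(.data$arm == "placebo", .data$formulation == cmp$formulation,
               .data$timepoint == cmp$timepoint) |>
        select("protein_id", "subject_id", ref = "intensity")
    }
    pairs <- inner_join(treat, ref, by = c("protein_id", "subject_id"))
    n_subj <- dplyr::n_distinct(pairs$subject_id)
    if (n_subj < 2) {
      abort(sprintf("comparison '%s': fewer than 2 subjects with a complete pair",
                    cmp$label))
    }
    usable <- pairs |>
      group_by(.data$protein_id) |>
      summarise(ok = all(.data$treat > 0 & .data$ref > 0) & n() == n_subj,
                .groups = "drop")
    excluded <- usable$protein_id[!usable$ok]
    if (length(excluded)) {
      warn(sprintf(
        "comparison '%s': excluded %d protein(s) with zero/missing intensities",
        cmp$label, length(excluded)))
    }
    wide <- pairs |>
      filter(!.data$protein_id %in% excluded) |>
      mutate(diff = log2(.data$treat / .data$ref)) |>
      select("protein_id", "subject_id", "diff") |>
      tidyr::pivot_wider(names_from = "subject_id", values_from = "diff")
    dm <- as.matrix(wide[, -1])
    k <- ncol(dm)
    mu <- rowMeans(dm)
    sdv <- sqrt(rowSums((dm - mu)^2) / (k - 1))
    tstat <- ifelse(sdv > 0, mu / (sdv / sqrt(k)), NA_real_)
    pval <- ifelse(sdv > 0, 2 * pt(-abs(tstat), df = k - 1),
                   ifelse(mu == 0, 1, NA_real_))
    deg <- which(sdv == 0 & mu != 0)
    if (length(deg)) {
      warn(sprintf(
        "comparison '%s': %d protein(s) with degenerate nonzero ratios excluded",
        cmp$label, length(deg)))
    }
    keep <- !is.na(pval)
    tibble(
      comparison = cmp$label,
      protein_id = wide$protein_id[keep],
      estimate = mu[keep],
      statistic = tstat[keep],
      df = k - 1,
      p_value = pval[keep],
      n = k
    ) |>
      mutate(q_value = bh_adjust(.data$p_value),
             significant = .data$q_value < q_threshold)
  })
  out <- list_rbind(rows) |>
    select("comparison", "protein_id", "estimate", "statistic", "df",
           "p_value", "q_value", "significant", "n")
  class(out) <- c("proteome_results", class(out))
  attr(out, "q_threshold") <- q_threshold
  out
}

check_long <- function(data, value_col) {
  need <- c("sample_id", value_col)
  feature <- intersect(c("protein_id", "taxon_id"), names(data))
  if (!all(need %in% names(data)) || length(feature) == 0) {
    abort(sprintf("expected a long tibble with columns %s and a feature id",
                  toString(need)))
  }
  if (any(data[[value_col]] < 0, na.rm = TRUE)) {
    abort(sprintf("negative %s values are not allowed", value_col))
  }
  invisible(data)
}
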