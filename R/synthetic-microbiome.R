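#' Generate a synthetic crossover microbiome study
#'
#' Simulates the 16S count layer of the crossover design: each subject
#' contributes `n_microbiome_baselines` study-baseline swabs plus pre-gel
#' (t0), 24 h and 7 d swabs for every arm x formulation cell (14 samples per
#' subject at the defaults). Per-subject baseline compositions are
#' logistic-normal around a long-tailed mean rank-abundance profile; each
#' sample adds diagonal logistic-normal noise on the log10 scale; taxa listed
#' in `config$effect_taxa` have their proportion multiplied by
#' `10^log10_ratio` (before renormalization) in samples at
#' (`effect_arm`, `effect_formulation`, `effect_timepoint`); read counts are
#' multinomial at a per-sample depth drawn log-normally around `mean_depth`.
#'
#' @param config A [study_config()].
#' @return A list of class `microbiome_study` with elements
#'   \describe{
#'     \item{counts}{long tibble `taxon_id`, `sample_id`, `count`}
#'     \item{meta}{`sample_id`, `subject_id`, `arm`, `formulation`,
#'       `timepoint`, `total_reads`}
#'     \item{truth}{planted effects, per-sample true proportions and true
#'       Shannon diversity}
#'   }
#' @examples
#' st <- gen_microbiome_study(study_config(n_taxa = 20, mean_depth = 1000, seed = 1))
#' sum(st$counts$count) == sum(st$meta$total_reads)
#' @export
gen_microbiome_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed + 1L)

  effect_tp <- config$effect_timepoint %||% "24h"
  subjects <- sprintf("subj%d", seq_len(config$n_subjects))
  taxon_ids <- sprintf("taxon%03d", seq_len(config$n_taxa))

  meta <- bind_rows(
    tidyr::expand_grid(
      subject_id = subjects,
      rep = seq_len(config$n_microbiome_baselines)
    ) |>
      mutate(arm = NA_character_, formulation = NA_character_,
             timepoint = "baseline",
             sample_id = sprintf("%s_mb_baseline_%d", .data$subject_id, .data$rep)) |>
      select(-"rep"),
    tidyr::expand_grid(
      subject_id = subjects,
      arm = c("placebo", "grft"),
      formulation = c("hec", "carbopol"),
      timepoint = c("t0", "24h", "7d")
    ) |>
      mutate(sample_id = sprintf("%s_mb_%s_%s_%s", .data$subject_id,
                                 .data$formulation, .data$arm, .data$timepoint))
  ) |>
    select("sample_id", "subject_id", "arm", "formulation", "timepoint")

  # long-tailed mean profile and per-subject baseline compositions (log10)
  mean_log10 <- rnorm(config$n_taxa, 0, config$taxa_spread_sd)
  subj_log10 <- matrix(
    mean_log10 + rnorm(config$n_taxa * config$n_subjects, 0, 0.3),
    nrow = config$n_taxa, dimnames = list(taxon_ids, subjects)
  )
  subj_prop <- apply(10^subj_log10, 2, function(p) p / sum(p))

  treated <- !is.na(meta$arm) &
    meta$arm == config$effect_arm &
    meta$formulation == config$effect_formulation &
    meta$timepoint == effect_tp

  n_samples <- nrow(meta)
  log10_p <- log10(subj_prop[, meta$subject_id, drop = FALSE]) +
    matrix(rnorm(config$n_taxa * n_samples, 0, config$comp_noise_sd),
           nrow = config$n_taxa)
  if (nrow(config$effect_taxa) > 0 && any(treated)) {
    idx <- config$effect_taxa$taxon
    log10_p[idx, treated] <- log10_p[idx, treated, drop = FALSE] +
      config$effect_taxa$log10_ratio
    perturbed_mass <- colSums(10^log10_p[idx, treated, drop = FALSE])
    if (any(perturbed_mass > 1)) {
      abort(sprintf(
        "perturbed proportions of the effect taxa sum to > 1 in sample(s) %s",
        toString(meta$sample_id[treated][perturbed_mass > 1])))
    }
  }
  true_prop <- apply(10^log10_p, 2, function(p) p / sum(p))
  dimnames(true_prop) <- list(taxon_ids, meta$sample_id)

  if (config$depth_dispersion == 0) {
    depths <- rep(round(config$mean_depth), n_samples)
  } else {
    depths <- pmax(1L, round(config$mean_depth *
      exp(rnorm(n_samples, -config$depth_dispersion^2 / 2,
                config$depth_dispersion))))
  }
  counts_mat <- vapply(seq_len(n_samples),
                       function(j) rmultinom(1, depths[j], true_prop[, j])[, 1],
                       integer(config$n_taxa))
  dimnames(counts_mat) <- list(taxon_ids, meta$sample_id)

  meta$total_reads <- as.integer(depths)
  counts <- mat_to_long(counts_mat, "taxon_id", "count")
  counts$count <- as.integer(counts$count)

  truth <- list(
    effect_taxa = mutate(config$effect_taxa,
                         taxon_id = taxon_ids[.data$taxon]),
    effect_arm = config$effect_arm,
    effect_formulation = config$effect_formulation,
    effect_timepoint = effect_tp,
    subject_baseline = mat_to_long(subj_prop, "taxon_id", "proportion") |>
      rename(subject_id = "sample_id"),
    true_proportions = mat_to_long(true_prop, "taxon_id", "proportion"),
    true_shannon = tibble(
      sample_id = meta$sample_id,
      shannon = apply(true_prop, 2, shannon)
    )
  )

  structure(list(counts = counts, meta = meta, truth = truth, config = config),
            class = "microbiome_study")
}

#' Generate replicate positive-control samples
#'
#' Replicate sequencing runs of one fixed mixed specimen, used to calibrate
#' the measurement-error model. Observed per-taxon log10 relative abundances
#' scatter around the true composition with a standard deviation that grows
#' as abundance falls:
#' `sigma(m) = pc_sigma_floor + pc_sigma_slope * pmax(0, pc_sigma_knee - m)`
#' at true median log10 abundance `m`. Counts are multinomial at the
#' configured depth, so very rare taxa carry additional counting noise on
#' top of the law.
#'
#' @param config A [study_config()]; needs `n_positive_controls >= 3`.
#' @param composition Optional fixed composition (positive vector, one entry
#'   per taxon; normalized internally). Default: drawn from the same
#'   rank-abundance law as the study communities.
#' @param depth Optional per-replicate depth; default `config$mean_depth`.
#' @return A list of class `positive_controls` with `counts`, `meta`
#'   (`sample_id`, `total_reads`) and `truth` (composition and the variance
#'   law).
#' @examples
#' pc <- gen_positive_controls(study_config(n_taxa = 10, seed = 1))
#' dplyr::n_distinct(pc$counts$sample_id)
#' @export
gen_positive_controls <- function(config, composition = NULL, depth = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (config$n_positive_controls < 3) {
    abort("need at least 3 positive-control replicates")
  }
  set.seed(config$seed + 2L)
  depth <- depth %||% config$mean_depth

  if (is.null(composition)) {
    composition <- 10^rnorm(config$n_taxa, 0, config$taxa_spread_sd)
  } else if (length(composition) != config$n_taxa || any(composition <= 0)) {
    abort("`composition` must be a positive vector of length n_taxa")
  }
  composition <- composition / sum(composition)
  taxon_ids <- sprintf("taxon%03d", seq_len(config$n_taxa))
  sample_ids <- sprintf("poscon%02d", seq_len(config$n_positive_controls))

  m <- log10(composition)
  sigma_law <- config$pc_sigma_floor +
    config$pc_sigma_slope * pmax(0, config$pc_sigma_knee - m)

  log10_obs <- matrix(
    m + rnorm(config$n_taxa * config$n_positive_controls, 0, sigma_law),
    nrow = config$n_taxa
  )
  prop_obs <- apply(10^log10_obs, 2, function(p) p / sum(p))
  counts_mat <- vapply(seq_len(config$n_positive_controls),
                       function(j) rmultinom(1, round(depth), prop_obs[, j])[, 1],
                       integer(config$n_taxa))
  dimnames(counts_mat) <- list(taxon_ids, sample_ids)

  counts <- mat_to_long(counts_mat, "taxon_id", "count")
  counts$count <- as.integer(counts$count)

  structure(list(
    counts = counts,
    meta = tibble(sample_id = sample_ids,
                  total_reads = as.integer(colSums(counts_mat))),
    truth = list(composition = setNames(composition, taxon_ids),
                 sigma_law = tibble(taxon_id = taxon_ids, m = m,
                                    sigma = sigma_law),
                 floor = config$pc_sigma_floor,
                 slope = config$pc_sigma_slope,
                 knee = config$pc_sigma_knee)
  ), class = "positive_controls")
}
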