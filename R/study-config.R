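#' Configuration of a synthetic crossover safety study
#'
#' Bundles every knob of the synthetic-data generators: study dimensions
#' (subjects, features, sequencing depth), the two-arm / two-formulation
#' crossover layout, planted true effects, and noise levels. Defaults mirror
#' a six-subject non-human-primate crossover design: 382 proteins measured at
#' 4 baseline time points plus pre-gel/2 h/24 h swabs per arm and formulation
#' (96 proteome samples), ~120 taxa sequenced at a mean depth of 58,671 reads
#' across 2 baseline plus pre-gel/24 h/7 d swabs per arm and formulation
#' (84 microbiome samples), 9 technical replicates of a pooled reference, and
#' 14 positive-control replicates.
#'
#' @param n_subjects Number of subjects (animals). Default 6.
#' @param n_proteins Number of proteins in the proteome table. Default 382.
#' @param n_taxa Number of taxa in the microbiome table. Default 120.
#' @param mean_depth Mean sequencing depth (reads/sample). Default 58671.
#' @param depth_dispersion Log-normal dispersion of per-sample depth around
#'   `mean_depth` (sd on the natural-log scale); 0 gives every sample exactly
#'   `mean_depth` reads. Default 0.3.
#' @param n_baseline_timepoints Proteome baseline time points per subject,
#'   averaged downstream into the baseline reference. Default 4.
#' @param n_microbiome_baselines Study-baseline microbiome swabs per subject.
#'   Default 2.
#' @param effect_taxa Data frame with columns `taxon` (1-based index) and
#'   `log10_ratio`: taxa truly perturbed in the treated samples. Default none.
#' @param effect_proteins Data frame with columns `protein` (1-based index)
#'   and `log2fc`: proteins truly perturbed in the treated samples.
#'   Default none.
#' @param effect_arm,effect_formulation,effect_timepoint Where the planted
#'   effects act. Defaults `"placebo"`, `"hec"`, and `"2h"` (proteome) /
#'   `"24h"` (microbiome, used when the timepoint is absent from that assay).
#' @param within_pair_sd_log2 Standard deviation of a within-subject paired
#'   log2 difference for a null protein. Default 1.603, the noise level at
#'   which a 6-pair design detects |2.3 log2 FC| with 80% power at alpha 0.05.
#' @param comp_noise_sd Sd (log10 scale) of the per-sample logistic-normal
#'   compositional noise in the microbiome generator. Default 0.15.
#' @param taxa_spread_sd Sd (log10 scale) of the spread of mean taxon
#'   abundances; larger values give a longer-tailed rank-abundance curve.
#'   Default 1.0.
#' @param n_tech_replicates Technical replicates of the pooled proteome
#'   reference. Default 9.
#' @param tech_replicate_cv Intensity-scale coefficient of variation of a
#'   well-behaved protein across technical replicates. Default 0.10.
#' @param cv_decoy_proteins Integer indices of proteins given a high
#'   technical-replicate CV (`cv_decoy_level`) so the replicate-CV filter has
#'   true positives to remove. Default none.
#' @param cv_decoy_level Intensity-scale CV of decoy proteins. Default 0.6.
#' @param n_positive_controls Replicate positive-control samples. Default 14.
#' @param pc_sigma_floor,pc_sigma_slope,pc_sigma_knee Parameters of the
#'   positive-control variance law: the sd of a taxon's log10 relative
#'   abundance across replicates is
#'   `pc_sigma_floor + pc_sigma_slope * pmax(0, pc_sigma_knee - m)` at median
#'   log10 abundance `m`, so rare taxa are noisier. Defaults 0.05, 0.1, -2.
#' @param seed Integer seed making every generator call deterministic.
#'
#' @return A list of class `study_config`.
#' @examples
#' cfg <- study_config(n_subjects = 6, n_taxa = 30, seed = 1)
#' cfg$mean_depth
#' @export
study_config <- function(n_subjects = 6,
                         n_proteins = 382,
                         n_taxa = 120,
                         mean_depth = 58671,
                         depth_dispersion = 0.3,
                         n_baseline_timepoints = 4,
                         n_microbiome_baselines = 2,
                         effect_taxa = NULL,
                         effect_proteins = NULL,
                         effect_arm = "placebo",
                         effect_formulation = "hec",
                         effect_timepoint = NULL,
                         within_pair_sd_log2 = 1.603,
                         comp_noise_sd = 0.15,
                         taxa_spread_sd = 1.0,
                         n_tech_replicates = 9,
                         tech_replicate_cv = 0.10,
                         cv_decoy_proteins = integer(0),
                         cv_decoy_level = 0.6,
                         n_positive_controls = 14,
                         pc_sigma_floor = 0.05,
                         pc_sigma_slope = 0.1,
                         pc_sigma_knee = -2,
                         seed = 1L) {
  counts <- c(
    n_subjects = n_subjects, n_proteins = n_proteins, n_taxa = n_taxa,
    n_baseline_timepoints = n_baseline_timepoints,
    n_microbiome_baselines = n_microbiome_baselines
  )
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a single integer >= 1 (got %s)", nm, format(v)))
    }
  }
  if (mean_depth < 1) abort("`mean_depth` must be >= 1")
  positives <- c(
    within_pair_sd_log2 = within_pair_sd_log2, comp_noise_sd = comp_noise_sd,
    taxa_spread_sd = taxa_spread_sd, depth_dispersion = depth_dispersion,
    tech_replicate_cv = tech_replicate_cv, cv_decoy_level = cv_decoy_level,
    pc_sigma_floor = pc_sigma_floor, pc_sigma_slope = pc_sigma_slope
  )
  for (nm in names(positives)) {
    if (positives[[nm]] < 0) abort(sprintf("`%s` must be >= 0", nm))
  }

  effect_taxa <- normalize_effect_table(effect_taxa, c("taxon", "log10_ratio"),
    n_taxa, "taxon")
  effect_proteins <- normalize_effect_table(effect_proteins,
    c("protein", "log2fc"), n_proteins, "protein")

  arm_levels <- c("placebo", "grft")
  form_levels <- c("hec", "carbopol")
  if (!effect_arm %in% arm_levels) {
    abort(sprintf("`effect_arm` must be one of %s", toString(arm_levels)))
  }
  if (!effect_formulation %in% form_levels) {
    abort(sprintf("`effect_formulation` must be one of %s", toString(form_levels)))
  }
  if (!is.null(effect_timepoint) &&
      !effect_timepoint %in% c("t0", "2h", "24h", "7d")) {
    abort("`effect_timepoint` must be one of t0, 2h, 24h, 7d")
  }

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_proteins = as.integer(n_proteins),
    n_taxa = as.integer(n_taxa),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    n_baseline_timepoints = as.integer(n_baseline_timepoints),
    n_microbiome_baselines = as.integer(n_microbiome_baselines),
    effect_taxa = effect_taxa,
    effect_proteins = effect_proteins,
    effect_arm = effect_arm,
    effect_formulation = effect_formulation,
    effect_timepoint = effect_timepoint,
    within_pair_sd_log2 = within_pair_sd_log2,
    comp_noise_sd = comp_noise_sd,
    taxa_spread_sd = taxa_spread_sd,
    n_tech_replicates = as.integer(n_tech_replicates),
    tech_replicate_cv = tech_replicate_cv,
    cv_decoy_proteins = as.integer(cv_decoy_proteins),
    cv_decoy_level = cv_decoy_level,
    n_positive_controls = as.integer(n_positive_controls),
    pc_sigma_floor = pc_sigma_floor,
    pc_sigma_slope = pc_sigma_slope,
    pc_sigma_knee = pc_sigma_knee,
    seed = as.integer(seed)
  ), class = "study_config")
}

normalize_effect_table <- function(x, cols, n_max, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    out <- tibble(a = integer(0), b = numeric(0))
    names(out) <- cols
    return(out)
  }
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    abort(sprintf("effect table must have columns %s", toString(cols)))
  }
  x <- as_tibble(x)[cols]
  idx <- x[[cols[1]]]
  if (any(idx < 1 | idx > n_max | idx != round(idx))) {
    bad <- idx[idx < 1 | idx > n_max | idx != round(idx)]
    abort(sprintf("effect %s index out of range: %s", what, toString(bad)))
  }
  if (anyDuplicated(idx)) {
    abort(sprintf("duplicated effect %s index: %s", what,
                  toString(idx[duplicated(idx)])))
  }
  x[[cols[1]]] <- as.integer(idx)
  x
}

#' MCMC settings
#'
#' Chain count, total iterations per chain, and thinning interval. The first
#' half of each chain is treated as warm-up/adaptation and discarded; the
#' remaining iterations are thinned. The default (3 chains of 10,000
#' iterations, thinning 10) yields 500 retained draws per chain; the fast
#' profile used in tests (3 chains of 2,000, thinning 2) retains the same
#' number of draws from shorter chains.
#'
#' @param n_chains Number of chains (>= 2 so convergence can be assessed).
#' @param n_iter Total iterations per chain, including warm-up.
#' @param thin Thinning interval applied after warm-up.
#' @return A list of class `mcmc_settings`.
#' @examples
#' mcmc_settings()
#' fast_mcmc_settings()
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 10000, thin = 10) {
  if (n_chains < 1) abort("`n_chains` must be >= 1")
  if (n_iter < 4) abort("`n_iter` must be >= 4")
  if (thin < 1 || thin != round(thin)) abort("`thin` must be a positive integer")
  warmup <- floor(n_iter / 2)
  if ((n_iter - warmup) < thin) abort("no draws left after warm-up and thinning")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), warmup = as.integer(warmup)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
fast_mcmc_settings <- function(n_chains = 3, n_iter = 2000, thin = 2) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, thin = thin)
}

#' Comparison registries for the crossover design
#'
#' One registry encodes which (treatment, control) sample pairs each study
#' comparison uses, so the proteomics and microbiome stages cannot drift
#' apart. Each row defines one comparison: `type` is either `"vs_baseline"`
#' (a post-gel time point against the subject's baseline reference — the
#' averaged baseline profile for the proteome, the matched pre-gel T0 swab
#' for the microbiome) or `"grft_vs_placebo"` (active arm against placebo at
#' the matched time point within a formulation).
#'
#' @return A tibble with columns `label`, `type`, `arm`, `formulation`,
#'   `timepoint`.
#' @examples
#' microbiome_comparisons()
#' @export
proteome_comparisons <- function() {
  vsb <- tidyr::expand_grid(
    arm = c("placebo", "grft"),
    formulation = c("hec", "carbopol"),
    timepoint = c("t0", "2h", "24h")
  ) |>
    mutate(type = "vs_baseline")
  gvp <- tidyr::expand_grid(
    formulation = c("hec", "carbopol"),
    timepoint = c("2h", "24h")
  ) |>
    mutate(arm = "grft", type = "grft_vs_placebo")
  bind_rows(vsb, gvp) |>
    mutate(label = ifelse(.data$type == "vs_baseline",
      sprintf("%s %s %s vs baseline", .data$formulation, .data$arm, .data$timepoint),
      sprintf("%s grft %s vs placebo %s", .data$formulation, .data$timepoint,
              .data$timepoint))) |>
    select("label", "type", "arm", "formulation", "timepoint")
}

#' @rdname proteome_comparisons
#' @export
microbiome_comparisons <- function() {
  vsb <- tidyr::expand_grid(
    arm = c("placebo", "grft"),
    formulation = c("hec", "carbopol"),
    timepoint = c("24h", "7d")
  ) |>
    mutate(type = "vs_baseline")
  gvp <- tidyr::expand_grid(
    formulation = c("hec", "carbopol"),
    timepoint = c("24h", "7d")
  ) |>
    mutate(arm = "grft", type = "grft_vs_placebo")
  bind_rows(vsb, gvp) |>
    mutate(label = ifelse(.data$type == "vs_baseline",
      sprintf("%s %s %s vs baseline", .data$formulation, .data$arm, .data$timepoint),
      sprintf("%s grft %s vs placebo %s", .data$formulation, .data$timepoint,
              .data$timepoint))) |>
    select("label", "type", "arm", "formulation", "timepoint")
}
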