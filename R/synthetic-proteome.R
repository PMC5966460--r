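#' Generate a synthetic crossover proteome study
#'
#' Simulates the label-free proteomics layer of a two-arm, two-formulation
#' crossover design. Each subject contributes `n_baseline_timepoints`
#' baseline samples plus pre-gel (t0), 2 h and 24 h samples for every
#' arm x formulation cell; a pooled reference is measured as
#' `n_tech_replicates` technical replicates. Protein intensities are
#' log-normal around protein- and subject-specific means, spanning about
#' four orders of magnitude; proteins listed in `config$effect_proteins` are
#' shifted by their true log2 fold change only in samples at
#' (`effect_arm`, `effect_formulation`, `effect_timepoint`).
#'
#' @param config A [study_config()].
#' @return A list of class `proteome_study` with elements
#'   \describe{
#'     \item{abundance}{long tibble `protein_id`, `sample_id`, `intensity`}
#'     \item{meta}{sample metadata: `sample_id`, `subject_id`, `arm`,
#'       `formulation`, `timepoint`, `is_tech_replicate`}
#'     \item{truth}{planted effects and generator parameters}
#'   }
#' @examples
#' st <- gen_proteome_study(study_config(n_proteins = 20, seed = 1))
#' dplyr::count(st$meta, timepoint)
#' @export
gen_proteome_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)

  effect_tp <- config$effect_timepoint %||% "2h"
  subjects <- sprintf("subj%d", seq_len(config$n_subjects))
  protein_ids <- sprintf("P%03d", seq_len(config$n_proteins))

  study_meta <- bind_rows(
    tidyr::expand_grid(
      subject_id = subjects,
      rep = seq_len(config$n_baseline_timepoints)
    ) |>
      mutate(arm = NA_character_, formulation = NA_character_,
             timepoint = "baseline",
             sample_id = sprintf("%s_baseline_%d", .data$subject_id, .data$rep)) |>
      select(-"rep"),
    tidyr::expand_grid(
      subject_id = subjects,
      arm = c("placebo", "grft"),
      formulation = c("hec", "carbopol"),
      timepoint = c("t0", "2h", "24h")
    ) |>
      mutate(sample_id = sprintf("%s_%s_%s_%s", .data$subject_id,
                                 .data$formulation, .data$arm, .data$timepoint))
  ) |>
    mutate(is_tech_replicate = FALSE)

  tech_meta <- tibble(
    sample_id = sprintf("ref_rep%d", seq_len(config$n_tech_replicates)),
    subject_id = NA_character_, arm = NA_character_,
    formulation = NA_character_, timepoint = NA_character_,
    is_tech_replicate = TRUE
  )
  meta <- bind_rows(study_meta, tech_meta) |>
    select("sample_id", "subject_id", "arm", "formulation", "timepoint",
           "is_tech_replicate")

  # protein-level log2 means span ~4 orders of magnitude (sd 3.3 log2 ~ 1 log10)
  base_log2 <- rnorm(config$n_proteins, mean = 18, sd = 3.3)
  subj_offset <- matrix(rnorm(config$n_proteins * config$n_subjects, 0, 0.25),
                        nrow = config$n_proteins,
                        dimnames = list(protein_ids, subjects))

  n_study <- nrow(study_meta)
  noise_sd <- config$within_pair_sd_log2 / sqrt(2)
  log2_mat <- matrix(base_log2, nrow = config$n_proteins, ncol = n_study)
  log2_mat <- log2_mat + subj_offset[, study_meta$subject_id]

  treated <- !is.na(study_meta$arm) &
    study_meta$arm == config$effect_arm &
    study_meta$formulation == config$effect_formulation &
    study_meta$timepoint == effect_tp
  if (nrow(config$effect_proteins) > 0 && any(treated)) {
    log2_mat[config$effect_proteins$protein, treated] <-
      log2_mat[config$effect_proteins$protein, treated, drop = FALSE] +
      config$effect_proteins$log2fc
  }
  log2_mat <- log2_mat + matrix(rnorm(length(log2_mat), 0, noise_sd),
                                nrow = config$n_proteins)
  intensity <- 2^log2_mat
  dimnames(intensity) <- list(protein_ids, study_meta$sample_id)

  # pooled reference replicates: lognormal noise with the configured CV,
  # decoy proteins get a deliberately high CV
  ref_profile <- rowMeans(intensity)
  cv <- rep(config$tech_replicate_cv, config$n_proteins)
  cv[config$cv_decoy_proteins] <- config$cv_decoy_level
  sdlog <- sqrt(log(1 + cv^2))
  tech <- matrix(
    ref_profile * exp(rnorm(config$n_proteins * config$n_tech_replicates,
                            -sdlog^2 / 2, sdlog)),
    nrow = config$n_proteins,
    dimnames = list(protein_ids, tech_meta$sample_id)
  )

  abundance <- bind_rows(
    mat_to_long(intensity, "protein_id", "intensity"),
    mat_to_long(tech, "protein_id", "intensity")
  )

  truth <- list(
    effect_proteins = mutate(config$effect_proteins,
                             protein_id = protein_ids[.data$protein]),
    effect_arm = config$effect_arm,
    effect_formulation = config$effect_formulation,
    effect_timepoint = effect_tp,
    within_pair_sd_log2 = config$within_pair_sd_log2,
    tech_replicate_cv = cv,
    base_log2 = setNames(base_log2, protein_ids)
  )

  structure(list(abundance = abundance, meta = meta, truth = truth,
                 config = config),
            class = "proteome_study")
}

mat_to_long <- function(mat, feature_col, value_col) {
  out <- tibble(
    f = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    v = as.vector(mat)
  )
  names(out) <- c(feature_col, "sample_id", value_col)
  out
}

#' Laplace (double-exponential) random deviates
#'
#' @param n Number of deviates.
#' @param location Location parameter.
#' @param scale Scale parameter (> 0); the variance is `2 * scale^2`.
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' mean(rlaplace(1e4, location = 0.5, scale = 0.05))
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  if (scale <= 0) abort("`scale` must be > 0")
  u <- runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}
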