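#' Simulate a complete study
#'
#' Generates the proteome study, the microbiome study and the
#' positive-control replicates from one [study_config()].
#'
#' @param config A [study_config()].
#' @return List with elements `proteome`, `microbiome`, `positive_controls`.
#' @export
simulate_study <- function(config = study_config()) {
  list(
    proteome = gen_proteome_study(config),
    microbiome = gen_microbiome_study(config),
    positive_controls = gen_positive_controls(config)
  )
}

#' Write a simulated study to disk
#'
#' Emits the proteome intensity table, the microbiome count table and the
#' positive-control count table as TSV (features as rows, first column the
#' feature id), a combined sample-metadata TSV, and the simulation truth as
#' JSON. Outputs are byte-identical across runs with the same config.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    proteome = file.path(dir, "proteome_intensities.tsv"),
    microbiome = file.path(dir, "microbiome_counts.tsv"),
    positive_controls = file.path(dir, "positive_controls.tsv"),
    metadata = file.path(dir, "sample_metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_wide_tsv(study$proteome$abundance, "protein_id", "intensity",
                 paths["proteome"])
  write_wide_tsv(study$microbiome$counts, "taxon_id", "count",
                 paths["microbiome"])
  write_wide_tsv(study$positive_controls$counts, "taxon_id", "count",
                 paths["positive_controls"])
  meta <- bind_rows(
    mutate(study$proteome$meta, assay = "proteome", total_reads = NA_integer_),
    mutate(study$microbiome$meta, assay = "microbiome",
           is_tech_replicate = FALSE),
    mutate(study$positive_controls$meta, assay = "positive_control",
           subject_id = NA_character_, arm = NA_character_,
           formulation = NA_character_, timepoint = NA_character_,
           is_tech_replicate = FALSE)
  ) |>
    select("sample_id", "assay", "subject_id", "arm", "formulation",
           "timepoint", "is_tech_replicate", "total_reads")
  readr::write_tsv(meta, paths["metadata"], na = "")
  truth <- list(
    proteome = study$proteome$truth[c("effect_proteins", "effect_arm",
                                      "effect_formulation", "effect_timepoint",
                                      "within_pair_sd_log2")],
    microbiome = study$microbiome$truth[c("effect_taxa", "effect_arm",
                                          "effect_formulation",
                                          "effect_timepoint")],
    positive_controls = study$positive_controls$truth[c("floor", "slope",
                                                        "knee")],
    config = unclass(study$proteome$config)
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

write_wide_tsv <- function(long, feature_col, value_col, path) {
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = dplyr::all_of(value_col))
  readr::write_tsv(wide, path)
}

#' Read study tables from TSV
#'
#' `read_feature_tsv()` reads a wide feature-by-sample table (first column
#' the feature id) back into the package's long format;
#' `read_metadata_tsv()` reads the sample metadata written by
#' [write_study()].
#'
#' @param path File path.
#' @param value_col Name for the value column (`"intensity"` or `"count"`).
#' @return A long tibble / metadata tibble.
#' @export
read_feature_tsv <- function(path, value_col = "count") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  feature_col <- names(wide)[1]
  out <- tidyr::pivot_longer(wide, -1, names_to = "sample_id",
                             values_to = value_col)
  if (value_col == "count") out[[value_col]] <- as.integer(out[[value_col]])
  out[c(feature_col, "sample_id", value_col)]
}

#' @rdname read_feature_tsv
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", assay = "c", subject_id = "c",
                    arm = "c", formulation = "c", timepoint = "c",
                    is_tech_replicate = "l", total_reads = "i"
                  ))
}

#' Read a taxon count table from a BIOM file
#'
#' Thin wrapper over the biomformat package (must be installed) returning
#' the package's long count format.
#'
#' @param path Path to a BIOM (JSON or HDF5) file.
#' @return Long tibble `taxon_id`, `sample_id`, `count`.
#' @export
read_taxa_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("reading BIOM files requires the biomformat package")
  }
  b <- biomformat::read_biom(path)
  mat <- as.matrix(biomformat::biom_data(b))
  out <- mat_to_long(mat, "taxon_id", "count")
  out$count <- as.integer(round(out$count))
  out
}

#' Run the full analysis workflow
#'
#' End-to-end driver: proteome normalization, replicate-CV filtering,
#' outlier report and paired differential expression; measurement-error
#' calibration; and all microbiome comparisons (taxon models plus Shannon
#' diversity). Optionally writes the result tables and a reproducibility
#' log (thresholds, seeds, package versions) to `out_dir`.
#'
#' @param study A [simulate_study()] list, or equivalently a list with
#'   `proteome`, `microbiome`, `positive_controls` read from disk.
#' @param out_dir Optional output directory for TSV results and the run
#'   log.
#' @param settings An [mcmc_settings()] for the Bayesian stages.
#' @param proteome_q,taxa_q FDR thresholds (defaults 0.05 and 0.01).
#' @param cv_threshold,outlier_k Proteome pipeline thresholds.
#' @param freq,prevalence,min_subjects Taxa-filter thresholds.
#' @param seed Integer seed for the MCMC stages.
#' @param engine MCMC engine for the model fits.
#' @param proteome_comparison_set,microbiome_comparison_set Comparison
#'   registries; defaults cover the full crossover design.
#' @return List of class `study_report`: `proteome` (results tibble),
#'   `outliers`, `microbiome` (a `study_results`), `error_model`, and the
#'   echoed configuration.
#' @export
run_study <- function(study, out_dir = NULL,
                      settings = mcmc_settings(),
                      proteome_q = 0.05, taxa_q = 0.01,
                      cv_threshold = 0.25, outlier_k = 1.5,
                      freq = 1e-5, prevalence = 0.25, min_subjects = 4,
                      seed = 1L, engine = "jags",
                      proteome_comparison_set = proteome_comparisons(),
                      microbiome_comparison_set = microbiome_comparisons()) {
  for (part in c("proteome", "microbiome", "positive_controls")) {
    if (is.null(study[[part]])) abort(sprintf("study is missing '%s'", part))
  }
  pmeta <- study$proteome$meta
  check_metadata(pmeta, c("sample_id", "subject_id", "arm", "formulation",
                          "timepoint", "is_tech_replicate"))
  mmeta <- study$microbiome$meta
  check_metadata(mmeta, c("sample_id", "subject_id", "arm", "formulation",
                          "timepoint", "total_reads"))

  norm <- study$proteome$abundance |>
    normalize_total_signal() |>
    filter_by_replicate_cv(pmeta, cv_threshold = cv_threshold) |>
    median_normalize()
  outliers <- flag_outlier_samples(
    filter(norm, .data$sample_id %in% pmeta$sample_id[!pmeta$is_tech_replicate]),
    k = outlier_k)
  proteome_res <- paired_differential(norm, pmeta,
                                      comparisons = proteome_comparison_set,
                                      q_threshold = proteome_q)

  error_model <- fit_measurement_error_model(study$positive_controls)
  microbiome_res <- run_all_comparisons(
    study$microbiome$counts, mmeta, error_model,
    settings = settings, comparisons = microbiome_comparison_set,
    freq = freq, prevalence = prevalence,
    min_subjects = min_subjects, q_threshold = taxa_q, seed = seed,
    engine = engine
  )

  report <- structure(list(
    proteome = proteome_res,
    outliers = outliers,
    microbiome = microbiome_res,
    error_model = error_model,
    thresholds = list(proteome_q = proteome_q, taxa_q = taxa_q,
                      cv_threshold = cv_threshold, outlier_k = outlier_k,
                      freq = freq, prevalence = prevalence,
                      min_subjects = min_subjects),
    settings = settings,
    seed = seed
  ), class = "study_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

check_metadata <- function(meta, required) {
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(sprintf("metadata is missing column(s): %s", toString(missing)))
  }
  invisible(meta)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(report$proteome, file.path(out_dir, "proteome_results.tsv"))
  readr::write_tsv(report$outliers, file.path(out_dir, "proteome_outliers.tsv"))
  readr::write_tsv(report$microbiome$taxa, file.path(out_dir, "taxa_results.tsv"))
  readr::write_tsv(report$microbiome$diversity,
                   file.path(out_dir, "diversity_results.tsv"))
  log <- list(
    package = "crossomics",
    version = as.character(packageVersion("crossomics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = report$seed,
    thresholds = report$thresholds,
    mcmc = unclass(report$settings)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  proteome: %d tests, %d significant at q < %g\n",
              nrow(x$proteome), sum(x$proteome$significant),
              x$thresholds$proteome_q))
  cat(sprintf("  outlier samples flagged: %d\n", sum(x$outliers$flagged)))
  cat(sprintf("  microbiome: %d taxon fits, %d significant at q < %g\n",
              nrow(x$microbiome$taxa), sum(x$microbiome$taxa$significant),
              x$thresholds$taxa_q))
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
glance.study_report <- function(x, ...) {
  tibble(
    proteome_tests = nrow(x$proteome),
    proteome_significant = sum(x$proteome$significant),
    outliers_flagged = sum(x$outliers$flagged),
    taxa_fits = nrow(x$microbiome$taxa),
    taxa_significant = sum(x$microbiome$taxa$significant)
  )
}
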