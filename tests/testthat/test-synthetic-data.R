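test_that("study_config validates dimensions and effect tables", {
  expect_s3_class(study_config(), "study_config")
  expect_error(study_config(n_subjects = 0), "n_subjects")
  expect_error(study_config(mean_depth = 0), "mean_depth")
  expect_error(
    study_config(n_proteins = 10,
                 effect_proteins = data.frame(protein = 11, log2fc = 1)),
    "out of range.*11")
  expect_error(
    study_config(n_taxa = 5,
                 effect_taxa = data.frame(taxon = c(2, 2),
                                          log10_ratio = c(1, 1))),
    "duplicated")
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- study_config(n_proteins = 15, n_taxa = 10, mean_depth = 2000,
                      seed = 11)
  expect_identical(gen_proteome_study(cfg)$abundance,
                   gen_proteome_study(cfg)$abundance)
  expect_identical(gen_microbiome_study(cfg)$counts,
                   gen_microbiome_study(cfg)$counts)
  expect_identical(gen_positive_controls(cfg)$counts,
                   gen_positive_controls(cfg)$counts)
})

test_that("proteome generator plants effects and respects the zero-noise limit", {
  cfg <- study_config(
    n_proteins = 10, seed = 1,
    effect_proteins = data.frame(protein = 1, log2fc = 3),
    within_pair_sd_log2 = 0.4
  )
  st <- gen_proteome_study(cfg)
  # mean treatment / baseline-average log2 ratio of the effect protein ~ 3
  base <- baseline_average(st$abundance, st$meta)
  treat <- dplyr::inner_join(
    dplyr::filter(st$abundance, .data$protein_id == "P001"),
    dplyr::filter(st$meta, arm == "placebo", formulation == "hec",
                  timepoint == "2h"),
    by = "sample_id")
  ratio <- dplyr::inner_join(treat,
                             dplyr::filter(base, protein_id == "P001"),
                             by = c("protein_id", "subject_id"))
  lfc <- mean(log2(ratio$intensity / ratio$baseline))
  expect_lt(abs(lfc - 3), 3 * 0.4 / sqrt(6))

  # zero within-pair noise: every null protein's paired log2 fc is exactly 0
  cfg0 <- study_config(n_proteins = 6, seed = 2, within_pair_sd_log2 = 0)
  st0 <- gen_proteome_study(cfg0)
  base0 <- baseline_average(st0$abundance, st0$meta)
  post <- dplyr::inner_join(
    st0$abundance,
    dplyr::filter(st0$meta, !is.na(arm)),
    by = "sample_id") |>
    dplyr::inner_join(base0, by = c("protein_id", "subject_id"))
  expect_equal(log2(post$intensity / post$baseline),
               rep(0, nrow(post)), tolerance = 1e-12)
})

test_that("microbiome count columns sum to their recorded depths", {
  cfg <- study_config(n_taxa = 15, mean_depth = 3000, seed = 4)
  st <- gen_microbiome_study(cfg)
  sums <- st$counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(count), .groups = "drop") |>
    dplyr::left_join(st$meta, by = "sample_id")
  expect_identical(sums$total, as.integer(sums$total_reads))

  # degenerate depth dispersion pins every sample at the mean depth
  st0 <- gen_microbiome_study(study_config(n_taxa = 8, mean_depth = 1234,
                                           depth_dispersion = 0, seed = 4))
  expect_true(all(st0$meta$total_reads == 1234L))
})

test_that("planted taxon effects are recovered by naive averaging; nulls stay null", {
  cfg <- study_config(
    n_taxa = 5, mean_depth = 50000, seed = 7, comp_noise_sd = 0.05,
    effect_taxa = data.frame(taxon = 3, log10_ratio = 0.352)
  )
  st <- gen_microbiome_study(cfg)
  cmp <- dplyr::filter(microbiome_comparisons(),
                       label == "hec placebo 24h vs baseline")
  pairs <- build_pairs(st$meta, cmp)
  pc <- st$counts |>
    dplyr::inner_join(dplyr::select(st$meta, sample_id, total_reads),
                      by = "sample_id") |>
    dplyr::mutate(rel = count / total_reads)
  rel_of <- function(samples) {
    dplyr::filter(pc, sample_id %in% samples, taxon_id == "taxon003")$rel
  }
  obs_ratio <- median(rel_of(pairs$treat_sample) / rel_of(pairs$control_sample))
  expect_lt(abs(log10(obs_ratio) - 0.352), 0.15)

  # null construction at larger n: per-taxon mean paired log10 ratio -> 0
  cfgn <- study_config(n_subjects = 60, n_taxa = 6, mean_depth = 20000,
                       comp_noise_sd = 0.1, seed = 8)
  stn <- gen_microbiome_study(cfgn)
  pairs_n <- build_pairs(stn$meta, cmp)
  dat <- stn$counts |>
    dplyr::inner_join(dplyr::select(stn$meta, sample_id, total_reads),
                      by = "sample_id")
  treat <- dplyr::inner_join(dat, tibble::tibble(
    sample_id = pairs_n$treat_sample, subject_id = pairs_n$subject_id),
    by = "sample_id")
  ctrl <- dplyr::inner_join(dat, tibble::tibble(
    sample_id = pairs_n$control_sample, subject_id = pairs_n$subject_id),
    by = "sample_id")
  both <- dplyr::inner_join(treat, ctrl, by = c("taxon_id", "subject_id"),
                            suffix = c("_t", "_c")) |>
    dplyr::filter(count_t > 0, count_c > 0) |>
    dplyr::group_by(taxon_id) |>
    dplyr::summarise(
      mean_lr = mean(log10((count_t / total_reads_t) /
                             (count_c / total_reads_c))),
      se = sd(log10((count_t / total_reads_t) /
                      (count_c / total_reads_c))) / sqrt(dplyr::n()),
      .groups = "drop")
  expect_true(all(abs(both$mean_lr) < 3 * both$se + 0.02))
})

test_that("effect taxa whose perturbed mass exceeds unity are rejected", {
  cfg <- study_config(n_taxa = 3, seed = 1, taxa_spread_sd = 0.01,
                      effect_taxa = data.frame(taxon = 1, log10_ratio = 2))
  expect_error(gen_microbiome_study(cfg), "sum to > 1")
})

test_that("positive controls follow the configured variance law", {
  cfg <- study_config(n_taxa = 50, n_positive_controls = 14, seed = 5)
  pc <- gen_positive_controls(cfg, depth = 1e6)
  dat <- pc$counts |>
    dplyr::inner_join(pc$meta, by = "sample_id") |>
    dplyr::filter(count > 0) |>
    dplyr::group_by(taxon_id) |>
    dplyr::filter(dplyr::n() == 14) |>
    dplyr::summarise(m = median(log10(count / total_reads)),
                     s = sd(log10(count / total_reads)), .groups = "drop") |>
    dplyr::inner_join(pc$truth$sigma_law, by = "taxon_id")
  # empirical sds track the generating law within Monte-Carlo error (14 reps)
  expect_gt(cor(dat$s, dat$sigma), 0.7)
  expect_lt(median(abs(dat$s - dat$sigma) / dat$sigma), 0.5)

  # 2-taxon 50/50 mixture at huge depth: log10 rel abundances ~ log10(0.5)
  cfg2 <- study_config(n_taxa = 2, n_positive_controls = 3,
                       pc_sigma_floor = 1e-4, seed = 6)
  pc2 <- gen_positive_controls(cfg2, composition = c(1, 1), depth = 1e7)
  rel <- pc2$counts$count /
    pc2$meta$total_reads[match(pc2$counts$sample_id, pc2$meta$sample_id)]
  expect_equal(log10(rel), rep(log10(0.5), 6), tolerance = 0.01)

  expect_error(
    gen_positive_controls(study_config(n_positive_controls = 2)),
    "at least 3")
})
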