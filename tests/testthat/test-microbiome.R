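test_that("taxa filtering enforces the three rules and is idempotent", {
  fx <- filter_fixture()
  out <- suppressMessages(filter_taxa(fx$counts, fx$meta, fx$pairs))
  expect_setequal(unique(out$taxon_id), fx$expected)

  dropped <- attr(out, "dropped")
  expect_match(dropped$reason[dropped$taxon_id == "tx05"], "frequency")
  expect_match(dropped$reason[dropped$taxon_id == "tx06"], "prevalence")
  expect_equal(dropped$reason[dropped$taxon_id == "tx08"], "min_subjects;")
  expect_equal(dropped$reason[dropped$taxon_id == "tx09"], "min_subjects;")

  again <- suppressMessages(filter_taxa(out, fx$meta, fx$pairs))
  expect_equal(dplyr::arrange(again, taxon_id, sample_id),
               dplyr::arrange(out, taxon_id, sample_id),
               ignore_attr = TRUE)

  strict <- dplyr::filter(fx$counts, count > 10^9)
  expect_error(filter_taxa(strict, fx$meta), "empty")
  only_rare <- dplyr::filter(fx$counts, taxon_id == "tx05")
  expect_error(suppressMessages(filter_taxa(only_rare, fx$meta)), "all taxa")
})

test_that("shannon diversity has its closed forms and maximal point", {
  expect_equal(shannon(rep(0.1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397207708399179,
               tolerance = 1e-12)
  expect_equal(shannon(c(0.5, 0.5, 0)), log(2), tolerance = 1e-12)
  expect_error(shannon(c(0.5, -0.1, 0.6)), "non-negative")
  expect_error(shannon(c(0.5, 0.4)), "sum to 1")

  # permutation invariance and maximum at uniform over small grids
  set.seed(6)
  for (k in c(3, 5, 8)) {
    p <- as.vector(rmultinom(1, 1000, runif(k))) / 1000
    expect_equal(shannon(p), shannon(sample(p)))
    expect_lte(shannon(p), shannon(rep(1 / k, k)) + 1e-12)
  }
})

test_that("the scaled-logit transform is centred, clamped and invertible", {
  expect_equal(logit_scaled_shannon(log(10) / 2, 10), 0, tolerance = 1e-12)
  expect_equal(logit_scaled_shannon(0, 50), -13.815509557963773,
               tolerance = 1e-9)
  set.seed(7)
  H <- runif(20, 0.05, 0.95) * log(30)
  expect_equal(inv_logit_scaled_shannon(logit_scaled_shannon(H, 30), 30), H,
               tolerance = 1e-10)
  expect_error(logit_scaled_shannon(log(10) + 0.1, 10), "outside")
  expect_error(logit_scaled_shannon(1, 1), "n_taxa")
})

test_that("the measurement-error calibration recovers a planted variance law", {
  cfg <- study_config(n_taxa = 50, n_positive_controls = 14,
                      pc_sigma_floor = 0.05, pc_sigma_slope = 0.1,
                      pc_sigma_knee = -2, seed = 5)
  pc <- gen_positive_controls(cfg, depth = 1e6)
  mem <- fit_measurement_error_model(pc)
  truth <- pc$truth$sigma_law
  pred <- predict(mem, truth$m)
  in_range <- truth$m > min(mem$range) & truth$m < max(mem$range)
  rel_err <- abs(pred[in_range] - truth$sigma[in_range]) /
    truth$sigma[in_range]
  expect_lt(median(rel_err), 0.3)
  expect_gt(mean(rel_err < 0.5), 0.8)

  # monotone non-increasing by construction; rare >= abundant
  expect_true(all(diff(predict(mem, seq(-6, -0.3, by = 0.1))) <= 1e-12))
  expect_gte(predict(mem, -4), predict(mem, -0.3))

  # degenerate replicates collapse to the floor
  fl <- floor_error_model()
  expect_equal(predict(fl, c(-1, -3, -5)), rep(1e-3, 3))

  few <- dplyr::filter(pc$counts, sample_id %in% c("poscon01", "poscon02"))
  expect_error(fit_measurement_error_model(few, pc$meta), "at least 3")
})

test_that("the diversity model recovers a planted Laplace location and nulls", {
  set.seed(11)
  yC <- rnorm(6, 0, 0.3)
  yT <- yC + rlaplace(6, 0.5, 0.05) + rnorm(6, 0, 0.05)
  fit <- fit_diversity_model(tibble::tibble(yT = yT, yC = yC),
                             fast_mcmc_settings(), seed = 1)
  g <- glance(fit)
  expect_true(g$conf.low < 0.5 && 0.5 < g$conf.high)
  expect_lt(g$psrf, 1.1)
  expect_true(g$converged)
  expect_equal(nrow(dplyr::filter(tidy(fit), grepl("^delta", term))), 6)

  # identical arms concentrate the location near zero
  y <- rnorm(6, 0, 0.4)
  fit0 <- fit_diversity_model(tibble::tibble(yT = y, yC = y),
                              fast_mcmc_settings(), seed = 2)
  expect_lt(abs(glance(fit0)$estimate), 0.05)
  expect_gt(glance(fit0)$p_value, 0.05)

  expect_error(fit_diversity_model(tibble::tibble(yT = 1:2, yC = 2:3)),
               "at least 3")
  expect_error(fit_diversity_model(tibble::tibble(yT = c(1, 2, Inf),
                                                  yC = c(1, 2, 3))),
               "finite")
})

test_that("the abundance model recovers effects, respects nulls, and skips empty arms", {
  mem <- floor_error_model(sigma_floor = 0.05)
  set.seed(12)
  tpC <- 0.01 * exp(rnorm(6, 0, 0.3))
  d <- make_taxon_pairs(tpC * 10^0.35, tpC, 50000L)
  fit <- fit_abundance_model(d, mem, fast_mcmc_settings(), seed = 1)
  g <- glance(fit)
  expect_lt(abs(g$estimate - 0.35), 0.15)
  expect_lt(g$p_value, 0.01)
  expect_lt(g$psrf, 1.1)

  d0 <- make_taxon_pairs(tpC, tpC, 50000L)
  g0 <- glance(fit_abundance_model(d0, mem, fast_mcmc_settings(), seed = 2))
  expect_lt(abs(g0$estimate), 0.1)
  expect_gt(g0$p_value, 0.01)

  # effect-size reading: posterior mean m corresponds to a 10^m-fold change
  expect_equal(10^0.301, 2, tolerance = 0.01)

  dz <- tibble::tibble(yT = c(0L, 0L, 0L), nT = 1000L,
                       yC = c(5L, 3L, 4L), nC = 1000L)
  expect_warning(out <- fit_abundance_model(dz, mem, fast_mcmc_settings()),
                 "zero counts")
  expect_null(out)
  expect_error(
    fit_abundance_model(tibble::tibble(yT = 2000L, nT = 1000L, yC = 1L,
                                       nC = 1000L), mem),
    "exceed")
})

test_that("abundance effects are equivariant under shifting the true ratio", {
  mem <- floor_error_model(sigma_floor = 0.05)
  set.seed(13)
  tpC <- 0.005 * exp(rnorm(6, 0, 0.2))
  shift <- 0.2
  d1 <- make_taxon_pairs(tpC * 10^0.1, tpC, 100000L)
  d2 <- make_taxon_pairs(tpC * 10^(0.1 + shift), tpC, 100000L)
  g1 <- glance(fit_abundance_model(d1, mem, fast_mcmc_settings(), seed = 3))
  g2 <- glance(fit_abundance_model(d2, mem, fast_mcmc_settings(), seed = 3))
  expect_equal(g2$estimate - g1$estimate, shift, tolerance = 0.1)
})

test_that("both MCMC engines sample the same posterior", {
  mem <- floor_error_model(sigma_floor = 0.05)
  set.seed(14)
  tpC <- 0.01 * exp(rnorm(6, 0, 0.2))
  d <- make_taxon_pairs(tpC * 10^0.3, tpC, 50000L)
  gj <- glance(fit_abundance_model(d, mem, fast_mcmc_settings(), seed = 1,
                                   engine = "jags"))
  gm <- glance(fit_abundance_model(
    d, mem, mcmc_settings(n_chains = 3, n_iter = 8000, thin = 4), seed = 2,
    engine = "metropolis"))
  expect_lt(abs(gj$estimate - gm$estimate), 0.06)

  set.seed(15)
  yC <- rnorm(6, 0, 0.3)
  yT <- yC + 0.4 + rnorm(6, 0, 0.1)
  dj <- glance(fit_diversity_model(tibble::tibble(yT = yT, yC = yC),
                                   mcmc_settings(), seed = 1))
  dm <- glance(fit_diversity_model(
    tibble::tibble(yT = yT, yC = yC),
    mcmc_settings(n_chains = 3, n_iter = 8000, thin = 4), seed = 2,
    engine = "metropolis"))
  expect_lt(abs(dj$estimate - dm$estimate), 0.08)
})
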