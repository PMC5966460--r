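make_long <- function(mat, value = "intensity") {
  tibble::tibble(
    protein_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    !!value := as.vector(mat)
  )
}

test_that("total-signal normalization equalizes totals and preserves proportions", {
  m <- matrix(c(60, 40, 110, 90), nrow = 2,
              dimnames = list(c("P1", "P2"), c("a", "b")))
  out <- normalize_total_signal(make_long(m))
  totals <- tapply(out$intensity, out$sample_id, sum)
  expect_equal(as.numeric(totals), c(150, 150))

  # identity when totals already equal
  m2 <- matrix(c(60, 40, 30, 70), nrow = 2,
               dimnames = list(c("P1", "P2"), c("a", "b")))
  expect_equal(normalize_total_signal(make_long(m2))$intensity,
               make_long(m2)$intensity)

  # proportions unchanged on a random matrix
  set.seed(1)
  m3 <- matrix(rexp(60), nrow = 10,
               dimnames = list(sprintf("P%d", 1:10), sprintf("s%d", 1:6)))
  d3 <- make_long(m3)
  out3 <- normalize_total_signal(d3)
  prop_before <- d3 |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(p = intensity / sum(intensity)) |>
    dplyr::pull(p)
  prop_after <- out3 |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(p = intensity / sum(intensity)) |>
    dplyr::pull(p)
  expect_equal(prop_after, prop_before, tolerance = 1e-12)

  m0 <- matrix(c(0, 0, 1, 2), nrow = 2,
               dimnames = list(c("P1", "P2"), c("bad", "ok")))
  expect_error(normalize_total_signal(make_long(m0)), "bad")
})

test_that("replicate-CV filter drops high-variance proteins only", {
  mat <- rbind(
    P1 = c(100, 100, 100, 80),
    P2 = c(100, 200, 150, 70),   # CV across replicates ~ 0.471
    P3 = c(50, 52, 48, 9000)
  )
  colnames(mat) <- c("r1", "r2", "r3", "study1")
  meta <- tibble::tibble(sample_id = colnames(mat),
                         is_tech_replicate = c(TRUE, TRUE, TRUE, FALSE))
  d <- make_long(mat)
  out <- suppressMessages(filter_by_replicate_cv(d, meta))
  expect_setequal(unique(out$protein_id), c("P1", "P3"))
  dropped <- attr(out, "dropped")
  expect_equal(dropped$protein_id, "P2")
  expect_equal(dropped$cv, sd(c(100, 200, 150)) / 150, tolerance = 1e-12)

  # an infinite threshold is the identity
  expect_equal(nrow(filter_by_replicate_cv(d, meta, cv_threshold = Inf)),
               nrow(d))
  expect_error(
    filter_by_replicate_cv(d, dplyr::mutate(meta, is_tech_replicate = FALSE)),
    "technical-replicate")
})

test_that("median normalization rescales to unit slope against the profile", {
  set.seed(2)
  base <- rexp(20) * 100
  m <- cbind(s1 = base, s2 = base * 2, s3 = base)
  rownames(m) <- sprintf("P%02d", 1:20)
  out <- median_normalize(make_long(m))
  wide <- tapply(out$intensity, list(out$protein_id, out$sample_id), c)
  # the doubled sample is scaled by exactly 1/2; profile samples unchanged
  expect_equal(unname(wide[, "s2"]), unname(wide[, "s1"]), tolerance = 1e-12)
  expect_equal(unname(wide[rownames(m), "s1"]), unname(base), tolerance = 1e-12)

  # random matrix: refitting against the median profile the normalization
  # used gives no-intercept slopes of exactly 1
  m2 <- matrix(rexp(80) * 50, nrow = 16,
               dimnames = list(sprintf("P%02d", 1:16), sprintf("s%d", 1:5)))
  profile <- apply(m2, 1, median)
  out2 <- median_normalize(make_long(m2))
  w2 <- tapply(out2$intensity, list(out2$protein_id, out2$sample_id), c)
  slopes <- apply(w2[names(profile), ], 2,
                  function(x) sum(profile * x) / sum(profile^2))
  expect_equal(unname(slopes), rep(1, 5), tolerance = 1e-8)

  const <- matrix(5, nrow = 3, ncol = 3,
                  dimnames = list(paste0("P", 1:3), paste0("s", 1:3)))
  expect_error(median_normalize(make_long(const)), "constant median profile")
})

test_that("outlier flagging reports IQR-fence deviants but keeps samples", {
  m <- matrix(1, nrow = 1, ncol = 5,
              dimnames = list("P1", paste0("s", 1:5)))
  m[1, ] <- c(10, 10, 10, 10, 100)
  rep_report <- flag_outlier_samples(make_long(m))
  expect_equal(rep_report$sample_id[rep_report$flagged], "s5")
  expect_equal(sum(rep_report$flagged), 1)

  # identical totals: IQR is 0, nothing deviates, nothing flagged
  m2 <- matrix(3, nrow = 2, ncol = 4,
               dimnames = list(c("P1", "P2"), paste0("s", 1:4)))
  expect_false(any(flag_outlier_samples(make_long(m2))$flagged))

  # 96-sample fixture with 3 planted extremes flags exactly those 3
  set.seed(3)
  totals <- runif(96, 950, 1050)  # bounded scatter: fences cannot catch it
  totals[c(10, 50, 90)] <- c(2000, 1900, 150)
  m3 <- matrix(totals, nrow = 1,
               dimnames = list("P1", sprintf("s%02d", 1:96)))
  m3 <- rbind(m3, P2 = 0)
  r3 <- flag_outlier_samples(make_long(m3))
  expect_setequal(r3$sample_id[r3$flagged], c("s10", "s50", "s90"))

  # quartile fences are wider than median fences
  rq <- flag_outlier_samples(make_long(m3), fence = "quartile")
  expect_true(all(rq$lower <= r3$lower) && all(rq$upper >= r3$upper))
})

test_that("baseline averaging is an arithmetic mean per subject", {
  meta <- tibble::tibble(
    sample_id = c("b1", "b2", "b3", "b4", "x1"),
    subject_id = "subj1",
    timepoint = c(rep("baseline", 4), "2h")
  )
  d <- tibble::tibble(protein_id = "P1",
                      sample_id = c("b1", "b2", "b3", "b4", "x1"),
                      intensity = c(2, 4, 6, 8, 99))
  expect_equal(baseline_average(d, meta)$baseline, 5)

  set.seed(4)
  vals <- rexp(4) * 10
  d2 <- tibble::tibble(protein_id = "P1", sample_id = paste0("b", 1:4),
                       intensity = vals)
  expect_equal(baseline_average(d2, meta[1:4, ])$baseline, mean(vals))

  meta_bad <- dplyr::mutate(meta, subject_id = c(rep("subj1", 4), "subj2"))
  expect_error(baseline_average(d, meta_bad), "subj2")
})

test_that("paired differential testing agrees with per-protein paired t tests", {
  cfg <- study_config(n_proteins = 40, seed = 9,
                      effect_proteins = data.frame(protein = 1:4, log2fc = 4),
                      within_pair_sd_log2 = 0.8)
  st <- gen_proteome_study(cfg)
  cmps <- dplyr::filter(proteome_comparisons(),
                        label == "hec placebo 2h vs baseline")
  res <- paired_differential(st$abundance, st$meta, cmps)

  # effect proteins called, and called only where planted
  expect_true(all(c("P001", "P002", "P003", "P004") %in%
                    res$protein_id[res$significant]))

  # cross-check one protein against the scalar paired_t_test route
  base <- baseline_average(st$abundance, st$meta)
  one <- st$abundance |>
    dplyr::filter(protein_id == "P007") |>
    dplyr::inner_join(dplyr::filter(st$meta, arm == "placebo",
                                    formulation == "hec", timepoint == "2h"),
                      by = "sample_id") |>
    dplyr::inner_join(base, by = c("protein_id", "subject_id")) |>
    dplyr::arrange(subject_id)
  oracle <- paired_t_test(log2(one$intensity / one$baseline))
  got <- dplyr::filter(res, protein_id == "P007")
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(got$estimate, oracle$estimate, tolerance = 1e-12)

  # all-equal treatment and reference: zero fold changes, nothing significant
  cfg0 <- study_config(n_proteins = 8, seed = 10, within_pair_sd_log2 = 0)
  st0 <- gen_proteome_study(cfg0)
  res0 <- paired_differential(st0$abundance, st0$meta, cmps)
  expect_true(all(res0$estimate == 0))
  expect_false(any(res0$significant))
  expect_true(all(res0$p_value == 1))

  # a single subject cannot be tested
  meta1 <- dplyr::filter(st$meta, subject_id %in% "subj1" | is_tech_replicate)
  d1 <- dplyr::semi_join(st$abundance, meta1, by = "sample_id")
  expect_error(paired_differential(d1, meta1, cmps), "fewer than 2 subjects")
})

test_that("the pipeline is deterministic end to end", {
  cfg <- study_config(n_proteins = 25, seed = 12)
  st <- gen_proteome_study(cfg)
  run_once <- function() {
    norm <- suppressMessages(normalize_proteome(st$abundance))
    paired_differential(norm, st$meta,
                        proteome_comparisons()[c(1, 9), ])
  }
  expect_identical(run_once(), run_once())
})

test_that("correlation-distance clustering matches a brute-force oracle", {
  # identical columns merge at distance 0
  set.seed(5)
  base <- rnorm(10)
  m <- cbind(a = base, b = base, c = rnorm(10), d = rnorm(10))
  rownames(m) <- sprintf("f%d", 1:10)
  cl <- hierarchical_cluster(m)
  expect_equal(min(cl$merge_heights), 0, tolerance = 1e-12)

  # anti-correlated columns sit at the maximal distance 2
  m2 <- cbind(x = base, y = -base, z = rnorm(10), w = rnorm(10))
  rownames(m2) <- rownames(m)
  d2 <- 1 - cor(m2)
  expect_equal(d2["x", "y"], 2, tolerance = 1e-12)

  # merge heights equal exhaustive complete-linkage agglomeration
  m3 <- matrix(rnorm(28), nrow = 7,
               dimnames = list(sprintf("f%d", 1:7), sprintf("s%d", 1:4)))
  cl3 <- hierarchical_cluster(m3)
  expect_equal(sort(cl3$merge_heights),
               complete_linkage_heights(1 - cor(m3)), tolerance = 1e-12)

  mc <- cbind(u = rep(1, 5), v = rnorm(5))
  rownames(mc) <- paste0("f", 1:5)
  expect_error(hierarchical_cluster(mc), "u")

  # newick export round-trips through ape
  nwk <- as_newick(cl3)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, colnames(m3))
})
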