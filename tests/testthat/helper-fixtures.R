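# Shared fixtures and independent oracles, all built in code.

# Brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over all
# p_(j) >= p_i of m * p_(j) / j, capped at 1. Written directly from the
# definition, independent of stats::p.adjust.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / seq(i, m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Brute-force complete-linkage agglomeration on a distance matrix: returns
# the multiset of merge heights. Independent of stats::hclust.
complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best[1]) best <- c(h, i, j)
        }
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# Measurement-error model pinned at its floor: calibrated on replicates with
# identical counts, so every empirical variance is zero.
floor_error_model <- function(sigma_floor = 1e-3) {
  counts <- tidyr::expand_grid(
    taxon_id = sprintf("t%02d", 1:8),
    sample_id = sprintf("rep%d", 1:4)
  )
  counts$count <- rep(c(1000L, 500L, 250L, 125L, 3000L, 100L, 10L, 15L),
                      each = 4)
  meta <- dplyr::summarise(dplyr::group_by(counts, sample_id),
                           total_reads = sum(count), .groups = "drop")
  suppressWarnings(
    fit_measurement_error_model(counts, meta, sigma_floor = sigma_floor)
  )
}

# Paired counts for one taxon at given true proportions and depth.
make_taxon_pairs <- function(tpT, tpC, depth) {
  tibble::tibble(
    yT = rbinom(length(tpT), depth, tpT), nT = depth,
    yC = rbinom(length(tpC), depth, tpC), nC = depth
  )
}

# Ten-taxon count table engineered against the three filtering rules so that
# exactly taxa 1-4 survive: taxon 5 fails the study-wide frequency rule,
# taxa 6-7 the prevalence rule, taxa 8-9 the within-comparison subject rule,
# and taxon 10 fails everything.
filter_fixture <- function() {
  subjects <- sprintf("s%d", 1:6)
  meta <- tidyr::expand_grid(subject_id = subjects,
                             timepoint = c("t0", "24h")) |>
    dplyr::mutate(sample_id = paste(subject_id, timepoint, sep = "_"),
                  arm = "placebo", formulation = "hec")
  depth <- 10000L
  mat <- matrix(0L, nrow = 10, ncol = nrow(meta),
                dimnames = list(sprintf("tx%02d", 1:10), meta$sample_id))
  mat[1:4, ] <- 200L                      # abundant, ubiquitous
  mat[5, ] <- rep(c(1L, 0L), 6)           # freq 5e-5... keep below 1e-5:
  mat[5, ] <- 0L; mat[5, 1] <- 1L         # one read study-wide -> freq ~8e-6
  mat[6, 1:2] <- 500L                     # 2/12 samples -> prevalence 1/6
  mat[7, 1:2] <- 400L
  mat[8, c(1, 3, 5)] <- 300L              # t0 of s1, s2, s3 -> 3 subjects
  mat[9, c(2, 4, 6)] <- 300L              # 24h of s1, s2, s3 -> 3 subjects
  # taxon 10: absent everywhere except negligible trace in one sample
  mat[10, 12] <- 1L
  counts <- tibble::tibble(
    taxon_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    count = as.integer(mat)
  )
  meta$total_reads <- depth
  pairs <- build_pairs(meta, tibble::tibble(
    label = "fixture", type = "vs_baseline", arm = "placebo",
    formulation = "hec", timepoint = "24h"))
  list(counts = counts, meta = meta, pairs = pairs,
       expected = sprintf("tx%02d", 1:4))
}
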