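flat_annotation <- function(df, lengths, centromeres = NULL) {
  structure(df, chrom_lengths = lengths, centromeres = centromeres,
            class = c("gene_annotation", "data.frame"))
}

test_that("frequency tracks count the fraction of aberrant samples", {
  segs <- do.call(rbind, lapply(1:19, function(i)
    data.frame(sample = paste0("s", i), chrom = "1",
               start = c(0, 400), end = c(400, 1000),
               value = c(if (i <= 6) 0.5 else 0, 0))))
  tr <- build_frequency_track(segs, "gain")
  expect_equal(tr$value[tr$start == 0], 6 / 19)
  expect_equal(tr$value[tr$start == 400], 0)

  # no gains anywhere: all-zero track
  segs0 <- transform(segs, value = 0)
  expect_true(all(build_frequency_track(segs0, "gain")$value == 0))

  # breakpoint union contains every input breakpoint
  segs2 <- rbind(segs,
                 data.frame(sample = "s20", chrom = "1",
                            start = c(0, 250), end = c(250, 1000),
                            value = c(0.5, -0.5)))
  tr2 <- build_frequency_track(segs2, "gain")
  expect_true(all(c(0, 250, 400, 1000) %in% c(tr2$start, tr2$end)))
})

test_that("mean_in_regions is the bp-weighted mean over gene-covered bases", {
  track <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200),
                      value = c(0.0, 1.0))
  genes <- flat_annotation(
    data.frame(chrom = "1", start = 50, end = 150, gene_id = "g1", arm = "p"),
    c("1" = 200))
  expect_equal(mean_in_regions(track, genes), 0.5)

  # a uniform track gives its value whatever the genes
  utrack <- transform(track, value = 0.37)
  expect_equal(mean_in_regions(utrack, genes), 0.37)

  # full gene coverage reduces to the bp-weighted track mean
  allg <- flat_annotation(
    data.frame(chrom = "1", start = 0, end = 200, gene_id = "g1", arm = "p"),
    c("1" = 200))
  track2 <- data.frame(chrom = "1", start = c(0, 60), end = c(60, 200),
                       value = c(0.2, 0.8))
  expect_equal(mean_in_regions(track2, allg),
               (60 * 0.2 + 140 * 0.8) / 200)

  # overlapping genes are flattened, not double counted
  dup <- flat_annotation(
    data.frame(chrom = "1", start = c(50, 50), end = c(150, 150),
               gene_id = c("g1", "g2"), arm = "p"),
    c("1" = 200))
  expect_equal(mean_in_regions(track, dup), 0.5)

  # zero coverage is not estimable
  far <- flat_annotation(
    data.frame(chrom = "2", start = 0, end = 10, gene_id = "g1", arm = "p"),
    c("2" = 100))
  expect_error(mean_in_regions(track, far),
               class = "triomics_not_estimable_error")

  # merging adjacent equal-value segments leaves the statistic unchanged
  split_track <- data.frame(chrom = "1", start = c(0, 50, 100),
                            end = c(50, 100, 200), value = c(0, 0, 1))
  expect_equal(mean_in_regions(split_track, genes),
               mean_in_regions(track, genes))
})

test_that("permutation p is deterministic, add-one bounded, 1 for constants", {
  track <- data.frame(chrom = "1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100), value = rep(0.4, 10))
  genes <- flat_annotation(
    data.frame(chrom = "1", start = 120, end = 380, gene_id = "g1",
               arm = "p"), c("1" = 1000))
  res <- permutation_test(track, genes, n_perm = 99L, seed = 1L)
  expect_equal(res$p_value, 1)    # constant track: every permutation ties

  track$value <- c(0.9, 0.8, 0.9, 0.1, 0.1, 0, 0, 0.1, 0, 0.1)
  r1 <- permutation_test(track, genes, n_perm = 199L, seed = 5L)
  r2 <- permutation_test(track, genes, n_perm = 199L, seed = 5L)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_error(permutation_test(track[1, ], genes),
               class = "triomics_not_estimable_error")
})

test_that("Monte Carlo p matches exhaustive enumeration on small tracks", {
  track <- data.frame(chrom = "1", start = seq(0, 500, 100),
                      end = seq(100, 600, 100),
                      value = c(0.9, 0.7, 0.4, 0.2, 0.1, 0.0))
  genes <- flat_annotation(
    data.frame(chrom = "1", start = c(10, 110), end = c(90, 200),
               gene_id = c("g1", "g2"), arm = "p"), c("1" = 600))
  w <- numeric(6)
  # oracle: recompute weights directly from interval arithmetic
  for (i in 1:6) {
    seg <- c(track$start[i], track$end[i])
    w[i] <- sum(pmax(0, pmin(seg[2], c(90, 200)) - pmax(seg[1], c(10, 110))))
  }
  obs <- sum(w * track$value) / sum(w)
  all_p <- all_permutations(track$value)
  stats_all <- vapply(all_p, function(v) sum(w * v) / sum(w), numeric(1))
  p_exact <- mean(stats_all >= obs - 1e-12)
  res <- permutation_test(track, genes, n_perm = 10000L, seed = 9L)
  expect_equal(res$observed, obs)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 1e-4)
})

test_that("per-arm tests stay inside their arm and are flagged when tiny", {
  genes <- flat_annotation(
    data.frame(chrom = "1", start = c(50, 150, 600, 700),
               end = c(120, 260, 660, 790),
               gene_id = paste0("g", 1:4), arm = c("p", "p", "q", "q")),
    c("1" = 1000), centromeres = c("1" = 400))
  track <- data.frame(chrom = "1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100),
                      value = c(0.8, 0.7, 0.6, 0.1, 0.1, 0.1, 0.2, 0.2,
                                0.1, 0.0))
  arms <- per_arm_tests(track, genes, n_perm = 199L, seed = 3L)
  expect_setequal(arms$arm, c("1p", "1q"))
  expect_true(all(arms$estimable))
  # p-arm segments end at the centromere, q-arm segments start there:
  # counts confirm the partition (segment 300-400 vs 400-500 split cleanly)
  expect_equal(arms$n_segments[arms$arm == "1p"], 4L)
  expect_equal(arms$n_segments[arms$arm == "1q"], 6L)

  # an arm with a single segment is flagged, not tested
  track1 <- data.frame(chrom = "1", start = c(0, 400), end = c(400, 1000),
                       value = c(0.5, 0.1))
  arms1 <- per_arm_tests(track1, genes, n_perm = 99L, seed = 3L)
  expect_false(any(arms1$estimable[arms1$arm == "1p"]))
})

test_that("gene-density-biased gains are detected with high power", {
  cfg <- simulation_config(n_chromosomes = 22L, genes_per_chromosome = 100L,
                           density_bias = 0.9, seed = 7L, planted = NULL)
  ann <- simulate_genome(cfg)
  ds <- simulate_dataset(cfg, ann)
  gain_tr <- build_frequency_track(ds$segments, "gain")
  res <- permutation_test(gain_tr, ann, n_perm = 1000L,
                          alternative = "greater", seed = 11L)
  expect_lte(res$p_value, 0.01)
  loss_tr <- build_frequency_track(ds$segments, "loss")
  res_l <- permutation_test(loss_tr, ann, n_perm = 1000L,
                            alternative = "less", seed = 12L)
  expect_lte(res_l$p_value, 0.01)
})
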