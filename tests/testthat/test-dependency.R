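test_that("contingency tables cross-tabulate the gene universe exactly", {
  genes <- paste0("g", 1:10)
  # 3 gained (g1,g2,g3), 4 over (g1,g2,g4,g5): both = 2 -> (2,1,2,5)
  hits <- list(
    gain = lapply(c("g1", "g2", "g3"), function(g) list(g, "s1")),
    over = lapply(c("g1", "g2", "g4", "g5"), function(g) list(g, "s1")))
  calls <- toy_calls(genes, "s1", hits)
  t <- make_table(calls, "s1", "gain", "over")
  expect_equal(unname(t), c(2L, 1L, 2L, 5L))
  expect_equal(sum(t), length(genes))
  expect_error(make_table(calls, "s1", "gain", "loss"),
               class = "triomics_input_error")
  # all-zero second channel collapses the a and c cells
  t0 <- make_table(calls, "s1", "gain", "hyper")
  expect_equal(unname(t0[c("a", "c")]), c(0L, 0L))
})

test_that("odds ratios match their closed form and the Haldane policy", {
  expect_equal(odds_ratio(c(2, 1, 2, 5)), 5.0)
  expect_equal(odds_ratio(c(0, 1, 1, 8)), (0.5 * 8.5) / (1.5 * 1.5))
  or_none <- odds_ratio(c(0, 1, 1, 8), zero_cell_policy = "none")
  expect_true(isTRUE(attr(or_none, "infinite")) || or_none == 0)
  # symmetry: swapping the two channels transposes the table (b <-> c)
  expect_equal(odds_ratio(c(2, 1, 2, 5)), odds_ratio(c(2, 2, 1, 5)))
})

test_that("table, odds ratio and chi-square agree with brute-force oracles", {
  # enumerate all 2x2 tables over a 6-gene universe by constructing the
  # corresponding call matrices and recounting gene by gene
  genes <- paste0("g", 1:6)
  for (a in 0:3) for (b in 0:2) for (cc in 0:2) {
    d <- 6L - a - b - cc
    if (d < 0) next
    A <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, cc, d))
    B <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, cc, d))
    hits <- list(gain = lapply(genes[A], function(g) list(g, "s1")),
                 over = lapply(genes[B], function(g) list(g, "s1")))
    t <- make_table(toy_calls(genes, "s1", hits), "s1", "gain", "over")
    # oracle: direct enumeration over genes
    expect_equal(unname(t),
                 c(sum(A & B), sum(A & !B), sum(!A & B), sum(!A & !B)))
    # odds-ratio oracle on the Haldane-corrected cells
    tc <- if (any(t == 0)) t + 0.5 else t
    expect_equal(odds_ratio(t), (tc[["a"]] * tc[["d"]]) /
                                 (tc[["b"]] * tc[["c"]]))
    # chi-square oracle: expected-count formula computed directly
    chi <- chi_square_p(t)
    m <- matrix(t, 2, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      expect_true(chi$degenerate)
      expect_equal(chi$p.value, 1)
    } else {
      E <- outer(rowSums(m), colSums(m)) / sum(m)
      stat <- sum((m - E)^2 / E)
      expect_equal(chi$statistic, stat, tolerance = 1e-12)
      expect_equal(chi$p.value, stats::pchisq(stat, 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("chi-square is transposition invariant and handles extremes", {
  expect_lt(chi_square_p(c(50, 0, 0, 50))$p.value, 1e-20)
  balanced <- chi_square_p(c(5, 5, 5, 5))
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p.value, 1)
  t1 <- chi_square_p(c(7, 3, 2, 9))
  t2 <- chi_square_p(c(7, 2, 3, 9))
  expect_equal(t1$statistic, t2$statistic)
})

test_that("p-value adjustment matches Bonferroni and a BH step-up oracle", {
  expect_equal(adjust_pvalues(rep(0.01, 12), "bonferroni")[1], 0.12)
  expect_equal(adjust_pvalues(rep(1, 5), "bh"), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:15, 1))
    expect_equal(adjust_pvalues(p, "bh"), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(numeric(0)), class = "triomics_input_error")
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "triomics_value_error")
})

test_that("two-way dependency analysis recovers planted associations", {
  cfg <- small_config(seed = 41L)
  ds <- simulate_small(cfg)
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  dep <- dependency_analysis(calls)
  expect_equal(nrow(dep), 12L * length(calls$samples))
  expect_true(all(dep$a + dep$b + dep$c + dep$d == length(calls$genes)))
  # dosage coupling makes gain/over-expression positively associated
  go <- dep[dep$combo == "gain+over", ]
  expect_gt(median(go$odds_ratio), 1)
  expect_gt(mean(go$p_adj < 0.05), 0.5)
  # OR symmetry between the two channel orderings
  t_ab <- make_table(calls, calls$samples[1], "gain", "over")
  t_ba <- make_table(calls, calls$samples[1], "over", "gain")
  expect_equal(odds_ratio(t_ab), odds_ratio(t_ba))
})

test_that("null data yield few significant dependencies", {
  # noisier platforms populate all six channels, so the 2x2 tables are
  # dense enough for the chi-square approximation to be meaningful
  n_sig <- 0L; n_tot <- 0L
  for (i in 1:25) {
    ds <- simulate_small(null_config(seed = 500L + i, noise_meth = 0.6,
                                     noise_expr = 0.6))
    calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                               ds$probe_map_meth, ds$probe_map_expr,
                               ds$annotation)
    for (method in c("bh", "bonferroni")) {
      dep <- dependency_analysis(calls, method = method)
      n_sig <- n_sig + sum(dep$p_adj < 0.05)
      n_tot <- n_tot + nrow(dep)
    }
  }
  expect_lte(n_sig / n_tot, 0.05)
})

test_that("conditional analysis isolates coupling inside the gain stratum", {
  # background methylation/expression noise high enough that every stratum
  # carries hyper-methylated and under-expressed genes (so off-target
  # strata are estimable), couplings removed, and a strong planted
  # hyper+under effect confined to gained genes
  cfg <- simulation_config(
    n_chromosomes = 10L, genes_per_chromosome = 180L, seed = 43L,
    meth_expr_coef = 0, cn_expr_coef = 0,
    noise_meth = 0.6, noise_expr = 0.6,
    delta_beta_effect = 0.75, expr_effect = 2.5,
    planted = list(list(label = "gain+hyper+under",
                        channels = c("gain", "hyper", "under"),
                        n_genes = 40L, n_samples = 12L)))
  ds <- simulate_small(cfg)
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  cond <- conditional_dependency(calls)
  gain_under <- cond[cond$cn_stratum == "gain" & cond$expr_state == "under", ]
  norm_under <- cond[cond$cn_stratum == "normal" &
                       cond$expr_state == "under" & cond$estimable, ]
  expect_gt(median(gain_under$odds_ratio, na.rm = TRUE), 1)
  expect_gt(mean(gain_under$p_adj < 0.05, na.rm = TRUE), 0.5)
  # hyper-methylation was planted only with gain: elsewhere OR stays near 1
  expect_lt(abs(log(median(norm_under$odds_ratio, na.rm = TRUE))), log(2))
  expect_lt(mean(norm_under$p_adj < 0.05, na.rm = TRUE), 0.2)
  # within a sample the non-empty strata partition the gene universe
  one <- cond[cond$sample == calls$samples[1], ]
  one <- one[one$a + one$b + one$c + one$d > 0, ]
  strat_size <- tapply(one$a + one$b + one$c + one$d, one$cn_stratum,
                       function(x) unique(x)[1])
  expect_equal(sum(strat_size), length(calls$genes))
})

test_that("empty strata are flagged not estimable", {
  genes <- paste0("g", 1:5)
  calls <- toy_calls(genes, "s1", list(hyper = list(list("g1", "s1"))))
  calls$cn_state <- matrix("normal", 5, 1, dimnames = list(genes, "s1"))
  cond <- conditional_dependency(calls)
  expect_true(all(!cond$estimable[cond$cn_stratum == "gain"]))
  expect_true(all(is.na(cond$p[cond$cn_stratum == "loss"])))
})
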