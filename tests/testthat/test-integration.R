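test_that("exactly 12 two-way and 8 three-way combinations exist", {
  combos <- enumerate_combos()
  expect_equal(sum(combos$n_way == 2L), 12L)
  expect_equal(sum(combos$n_way == 3L), 8L)
  expect_false(anyDuplicated(combos$label) > 0)
  # deterministic order
  expect_identical(combos$label, enumerate_combos()$label)
  # every triple projects onto exactly 3 of the 12 pairs
  two <- combos[combos$n_way == 2L, ]
  for (i in which(combos$n_way == 3L)) {
    tri <- combos[i, c("cn", "meth", "expr")]
    pairs <- c(paste(tri$cn, tri$meth, sep = "+"),
               paste(tri$cn, tri$expr, sep = "+"),
               paste(tri$meth, tri$expr, sep = "+"))
    expect_true(all(pairs %in% two$label))
  }
})

test_that("recurrence counts samples with all channels of a combo", {
  genes <- paste0("g", 1:3)
  samples <- paste0("s", 1:19)
  hits <- list(
    gain = c(lapply(1:6, function(i) list("g1", samples[i])),
             list(list("g2", "s1"))),
    hyper = c(lapply(1:6, function(i) list("g1", samples[i])),
              list(list("g2", "s2"))))
  rec <- recurrence(toy_calls(genes, samples, hits))
  expect_equal(rec$counts["g1", "gain+hyper"], 6L)
  # gain in s1, hyper in s2 only: no same-sample co-occurrence
  expect_equal(rec$counts["g2", "gain+hyper"], 0L)
  expect_equal(rec$counts["g3", "gain+hyper"], 0L)

  curve <- recurrence_curve(rec)
  for (cc in unique(curve$combo)) {
    ng <- curve$n_genes[curve$combo == cc]
    expect_true(all(diff(ng) <= 0))
  }
})

test_that("triple counts never exceed their pair projections", {
  ds <- simulate_small(small_config(seed = 23L))
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  rec <- recurrence(calls)
  combos <- rec$combos
  for (i in which(combos$n_way == 3L)) {
    tri <- combos[i, ]
    pairs <- c(paste(tri$cn, tri$meth, sep = "+"),
               paste(tri$cn, tri$expr, sep = "+"),
               paste(tri$meth, tri$expr, sep = "+"))
    pair_min <- do.call(pmin, lapply(pairs, function(p) rec$counts[, p]))
    expect_true(all(rec$counts[, tri$label] <= pair_min))
  }
})

test_that("selection uses strict >= k semantics and is nested in k", {
  genes <- paste0("g", 1:2)
  samples <- paste0("s", 1:19)
  hits <- list(
    gain = c(lapply(1:6, function(i) list("g1", samples[i])),
             lapply(1:5, function(i) list("g2", samples[i]))),
    over = c(lapply(1:6, function(i) list("g1", samples[i])),
             lapply(1:5, function(i) list("g2", samples[i]))))
  rec <- recurrence(toy_calls(genes, samples, hits))
  sel6 <- select_recurrent(rec, k = 6L)
  expect_identical(sel6$gene_id, "g1")
  expect_equal(sel6$count, 6L)
  expect_false("g2" %in% sel6$gene_id)     # count 5 at k=6 is out
  sel5 <- select_recurrent(rec, k = 5L)
  expect_true(all(sel6$gene_id %in% sel5$gene_id))
  sel1 <- select_recurrent(rec, k = 1L)
  expect_setequal(sel1$gene_id, c("g1", "g2"))
})

test_that("the union rule finds disjoint-mechanism genes and only those", {
  genes <- c("gU", "gP")
  samples <- paste0("s", 1:19)
  # gU: over+gain in s1-s3, over+hypo in s4-s6 -> union count 6, no pair >= 6
  # gP: gain+over in s1-s6 -> caught by the pairwise rule, excluded here
  hits <- list(
    over = c(lapply(1:6, function(i) list("gU", samples[i])),
             lapply(1:6, function(i) list("gP", samples[i]))),
    gain = c(lapply(1:3, function(i) list("gU", samples[i])),
             lapply(1:6, function(i) list("gP", samples[i]))),
    hypo = lapply(4:6, function(i) list("gU", samples[i])))
  calls <- toy_calls(genes, samples, hits)
  sel <- select_recurrent(recurrence(calls), k = 6L)
  expect_false("gU" %in% sel$gene_id)
  expect_true("gP" %in% sel$gene_id)
  uni <- select_union(calls, k = 6L)
  expect_identical(uni$gene_id, "gU")
  expect_equal(uni$count, 6L)
  expect_equal(uni$combo, "union_over")

  # empty calls give an empty selection
  empty <- toy_calls("g1", samples)
  expect_equal(nrow(select_union(empty, k = 6L)), 0L)
})

test_that("planted recurrent genes are recovered at k=6 with low FDP", {
  # no density bias: the only recurrent co-occurrence signal is planted,
  # so sensitivity and FDP against the planted list are well defined
  cfg <- simulation_config(n_chromosomes = 8L, genes_per_chromosome = 120L,
                           seed = 31L, density_bias = 0)
  ds <- simulate_small(cfg)
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  sel <- select_recurrent(recurrence(calls), k = 6L)
  planted_pairs <- ds$truth$gene_label$gene_id[
    ds$truth$gene_label$label %in% expression_consistent_pairs()]
  planted_all <- unique(ds$truth$gene_label$gene_id)
  sensitivity <- mean(planted_pairs %in% sel$gene_id)
  fdp <- mean(!unique(sel$gene_id) %in% planted_all)
  expect_gte(sensitivity, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("union selection is empty when only pair mechanisms are planted", {
  cfg <- small_config(seed = 37L,
                      planted = list(list(label = "gain+over",
                                          channels = c("gain", "over"),
                                          n_genes = 12L, n_samples = 8L)))
  ds <- simulate_small(cfg)
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  uni <- select_union(calls, k = 6L)
  expect_equal(nrow(uni[uni$gene_id %in% ds$truth$gene_label$gene_id, ]), 0L)
})
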