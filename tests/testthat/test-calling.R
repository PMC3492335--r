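toy_annotation <- function() {
  structure(
    data.frame(chrom = "1", start = c(0, 200), end = c(100, 300),
               gene_id = c("gA", "gB"), arm = "p"),
    chrom_lengths = c("1" = 1000), centromeres = c("1" = 400),
    class = c("gene_annotation", "data.frame"))
}

test_that("quantile normalization equalizes column distributions", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(x)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

  # already-identical columns are a fixed point
  y <- cbind(a = c(2, 7, 1), b = c(2, 7, 1))
  expect_equal(quantile_normalize(y)[, ], y[, ])

  # column means agree after normalization, ranks are preserved
  set.seed(1)
  z <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  qn <- quantile_normalize(z)
  expect_lt(diff(range(colMeans(qn))), 1e-12)
  for (j in 1:3) expect_equal(order(qn[, j]), order(z[, j]))
  expect_error(quantile_normalize(z[, 1, drop = FALSE]),
               class = "triomics_input_error")
})

test_that("gene copy-number states follow the segment value cuts", {
  ann <- toy_annotation()
  seg <- data.frame(sample = "s1", chrom = "1",
                    start = c(0, 150, 600), end = c(150, 600, 1000),
                    value = c(0.25, 0.0, -0.5))
  cn <- call_copy_number(seg, ann)
  expect_true(cn$gain["gA", "s1"])    # 0.25 >= 0.2
  expect_false(cn$gain["gB", "s1"])   # 0.0 inside (-0.2, 0.2)
  expect_equal(cn$state["gB", "s1"], "normal")
  expect_false(any(cn$conflict))
})

test_that("a gene spanning conflicting segments lands in both lists", {
  ann <- toy_annotation()
  seg <- data.frame(sample = "s1", chrom = "1",
                    start = c(0, 50, 100), end = c(50, 100, 1000),
                    value = c(0.3, -0.3, 0))
  cn <- call_copy_number(seg, ann)
  expect_true(cn$gain["gA", "s1"])
  expect_true(cn$loss["gA", "s1"])
  expect_true(cn$conflict["gA", "s1"])
})

test_that("genes on chromosomes missing from a track are skipped", {
  ann <- structure(
    data.frame(chrom = c("1", "2"), start = 0, end = 100,
               gene_id = c("gA", "gB"), arm = "p"),
    class = c("gene_annotation", "data.frame"))
  seg <- data.frame(sample = "s1", chrom = "1", start = 0, end = 1000,
                    value = 0.5)
  expect_warning(cn <- call_copy_number(seg, ann), "skipped")
  expect_true(is.na(cn$state["gB", "s1"]))
  expect_error(call_copy_number(seg, ann, missing_chrom = "error"),
               class = "triomics_chromosome_error")
})

test_that("delta is the case value minus the control mean", {
  x <- matrix(c(0.9, 0.3, 0.5), 1, dimnames = list("p1", c("s1", "c1", "c2")))
  attr(x, "role") <- "beta"
  d <- compute_delta(x, controls = c("c1", "c2"))
  expect_equal(unname(d["p1", "s1"]), 0.5)    # 0.9 - 0.4

  y <- matrix(c(8.2, 7.1, 6.9), 1, dimnames = list("p1", c("s1", "c1", "c2")))
  attr(y, "role") <- "vst"
  dy <- compute_delta(y, controls = c("c1", "c2"))
  expect_equal(unname(dy["p1", "s1"]), 1.2)
  calls <- call_probes(dy)
  expect_true(calls$over["p1", "s1"])         # 1.2 > 1

  expect_error(compute_delta(x, controls = c("c1", "nope")),
               class = "triomics_control_error")
  expect_error(compute_delta(x, controls = character(0)),
               class = "triomics_control_error")
})

test_that("probe calls use strict inequalities at the printed cuts", {
  d <- matrix(c(0.41, 0.40, -0.41, -0.40), 1,
              dimnames = list("p1", paste0("s", 1:4)))
  attr(d, "role") <- "beta"
  pc <- call_probes(d)
  expect_equal(unname(pc$hyper["p1", ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(pc$hypo["p1", ]), c(FALSE, FALSE, TRUE, FALSE))

  e <- matrix(c(1.0, 1.0 + 1e-9, -1.0, -1.2), 1,
              dimnames = list("p1", paste0("s", 1:4)))
  attr(e, "role") <- "vst"
  ec <- call_probes(e)
  expect_equal(unname(ec$over["p1", ]), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(ec$under["p1", ]), c(FALSE, FALSE, FALSE, TRUE))

  # all-zero delta yields no calls
  z <- matrix(0, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  attr(z, "role") <- "vst"
  expect_equal(sum(call_probes(z)$over), 0)
})

test_that("probe-to-gene collapse follows the inclusion rule", {
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("gA", "gA", "gB"))
  hyper <- matrix(c(TRUE, FALSE, FALSE), 3, 1,
                  dimnames = list(c("p1", "p2", "p3"), "s1"))
  hypo <- matrix(c(FALSE, TRUE, FALSE), 3, 1,
                 dimnames = list(c("p1", "p2", "p3"), "s1"))
  out <- collapse_to_genes(list(hyper = hyper, hypo = hypo), pm)
  # one hyper probe suffices; conflicting probes put the gene on both lists
  expect_true(out$hyper["gA", "s1"])
  expect_true(out$hypo["gA", "s1"])
  expect_false(out$hyper["gB", "s1"])

  # unmapped probes are dropped with a warning and counted
  pm2 <- pm[1:2, ]
  expect_warning(out2 <- collapse_to_genes(list(hyper = hyper), pm2),
                 "unmapped")
  expect_equal(attr(out2, "n_unmapped"), 1L)
})

test_that("raising a threshold never increases the number of calls", {
  ds <- simulate_small(small_config(seed = 13L))
  d <- compute_delta(ds$beta)
  cuts <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  n_hyper <- vapply(cuts, function(cc)
    sum(call_probes(d, default_thresholds(delta_beta = cc))$hyper),
    numeric(1))
  expect_true(all(diff(n_hyper) <= 0))

  de <- compute_delta(ds$expr)
  n_over <- vapply(c(0.5, 1, 1.5, 2), function(cc)
    sum(call_probes(de, default_thresholds(vst_ratio = cc))$over),
    numeric(1))
  expect_true(all(diff(n_over) <= 0))
})

test_that("calling is per-sample independent under column permutation", {
  ds <- simulate_small(small_config(seed = 17L))
  d <- compute_delta(ds$expr)
  pc <- call_probes(d)
  perm <- rev(seq_len(ncol(d)))
  d_perm <- d[, perm]
  attr(d_perm, "role") <- "vst"
  pc_perm <- call_probes(d_perm)
  expect_identical(pc_perm$over, pc$over[, perm])
})

test_that("the shared universe drops genes missing a platform", {
  cfg <- small_config(seed = 19L, probes_per_gene_meth = c(0L, 1L, 2L))
  ds <- simulate_small(cfg)
  calls <- build_call_matrix(ds$segments, ds$beta, ds$expr,
                             ds$probe_map_meth, ds$probe_map_expr,
                             ds$annotation)
  n_genes <- nrow(ds$annotation)
  expect_lt(length(calls$genes), n_genes)
  expect_setequal(calls$genes,
                  intersect(unique(ds$probe_map_meth$gene_id),
                            unique(ds$probe_map_expr$gene_id)))
})
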