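# Small fixture builders shared across the test files. Everything is
# generated in code; nothing is read from disk.

# a compact simulated cohort: 4 autosomes, 19 cases, 2 controls
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 4L, genes_per_chromosome = 50L, seed = seed),
    list(...), keep.null = TRUE)
  do.call(simulation_config, args)
}

# a null cohort: nothing planted, uniform density, no cross-platform
# coupling — channels are then independent by construction
null_config <- function(seed = 1L, ...) {
  small_config(seed = seed, planted = NULL, density_bias = 0,
               cn_expr_coef = 0, meth_expr_coef = 0, ...)
}

simulate_small <- function(config) {
  ann <- simulate_genome(config)
  ds <- simulate_dataset(config, ann)
  ds$annotation <- ann
  ds
}

# build a call_matrix directly from per-channel lists of gene x sample hits
toy_calls <- function(genes, samples, hits = list()) {
  channels <- lapply(call_channels(), function(ch) {
    m <- matrix(FALSE, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (h in hits[[ch]] %||% list()) m[h[[1]], h[[2]]] <- TRUE
    m
  })
  names(channels) <- call_channels()
  call_matrix(genes, samples, channels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent Benjamini-Hochberg step-up oracle: direct enumeration of the
# step-up rule, adj_i = min_{j >= rank(i)} m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj_sorted[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# enumerate all permutations of a vector (for exhaustive permutation nulls)
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(r) c(v[i], r)))
  out
}

# brute-force complete-linkage clustering: at each step merge the pair of
# clusters whose maximum inter-point distance is smallest (O(n^3))
complete_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights[step] <- best_h
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
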