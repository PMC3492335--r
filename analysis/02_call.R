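#!/usr/bin/env Rscript
# Stage 2 — per-gene aberration calling.
#
# Converts the three platforms into binary gene-by-sample calls over the
# six channels (gain, loss, hyper- and hypo-methylation, over- and
# under-expression) against the control average, using the standard cuts:
# segment log-ratio +/-0.2 for copy number, deltaBeta strictly beyond
# +/-0.4, vst ratio strictly beyond +/-1. Restricts to the shared universe
# (autosomal genes with a CN state and probes on both arrays).

suppressPackageStartupMessages(library(triomics))
dat <- "results/data"
out <- "results"

ann <- read_annotation(file.path(dat, "annotation.tsv"))
segments <- read_segments(file.path(dat, "segments.tsv"))
beta <- read_matrix(file.path(dat, "beta.tsv"))
expr <- read_matrix(file.path(dat, "expr.tsv"))
pm_meth <- read_probe_map(file.path(dat, "probe_map_meth.tsv"))
pm_expr <- read_probe_map(file.path(dat, "probe_map_expr.tsv"))

calls <- build_call_matrix(segments, beta, expr, pm_meth, pm_expr, ann)
write_calls(calls, file.path(out, "calls.tsv"))
counts <- call_counts(calls)
write.table(counts, file.path(out, "call_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("shared gene universe: %d of %d genes\n",
            length(calls$genes), nrow(ann)))
tot <- tapply(counts$n_genes, counts$channel, sum)
for (ch in call_channels())
  cat(sprintf("  %-5s %6d gene-sample calls (median %d per sample)\n", ch,
              tot[[ch]],
              round(median(counts$n_genes[counts$channel == ch]))))
cat(sprintf("copy-number conflict flags: %d\n", sum(calls$cn_conflict)))
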