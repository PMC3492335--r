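#!/usr/bin/env Rscript
# Stage 4 — per-sample dependency statistics.
#
# For every sample, cross-tabulates each two-way channel combination over
# the gene universe, computes the odds ratio (Haldane-corrected for zero
# cells) and the chi-square p-value, adjusted (Benjamini-Hochberg) within
# the sample's 12-combination family. Then conditions hyper-methylation
# versus expression state on the three-state copy number to ask whether
# the methylation-expression coupling differs between gained, normal and
# lost genes.

suppressPackageStartupMessages(library(triomics))
out <- "results"
dat <- "results/data"
calls <- read_calls(file.path(out, "calls.tsv"))

# the serialized call file carries binary channels only; recompute the
# three-state copy number for the conditional analysis
ann <- read_annotation(file.path(dat, "annotation.tsv"))
segments <- read_segments(file.path(dat, "segments.tsv"))
cn <- call_copy_number(segments, ann)
calls$cn_state <- cn$state[calls$genes, calls$samples]

dep <- dependency_analysis(calls, method = "bh")
cond <- conditional_dependency(calls, method = "bh")
write.table(dep, file.path(out, "dependency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cond, file.path(out, "dependency_conditional.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("median odds ratio (fraction of samples significant, BH<0.05):\n")
for (cc in unique(dep$combo)) {
  sub <- dep[dep$combo == cc, ]
  cat(sprintf("  %-12s OR %8.2f  (%2.0f%%)\n", cc, median(sub$odds_ratio),
              100 * mean(sub$p_adj < 0.05)))
}
gu <- cond[cond$cn_stratum == "gain" & cond$expr_state == "under" &
             cond$estimable, ]
cat(sprintf("gain stratum, hyper vs under-expression: median OR %.1f, %d/%d samples significant\n",
            median(gu$odds_ratio, na.rm = TRUE), sum(gu$p_adj < 0.05),
            nrow(gu)))
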