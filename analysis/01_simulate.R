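#!/usr/bin/env Rscript
# Stage 1 — simulate the three-platform cohort.
#
# Generates the synthetic study: 19 case cell lines and 2 normal control
# cultures over 22 autosomes (~11.8k genes), with segmented copy number,
# methylation beta values and vst-scale expression. Gains are biased toward
# gene-dense regions; recurrent two-way aberrations, one gain/hyper/under
# triple and one split-mechanism (gain-or-hypo with over-expression) set
# are planted with known truth. All downstream stages read the TSVs this
# stage writes under results/data/.

suppressPackageStartupMessages(library(triomics))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
ann <- simulate_genome(cfg)
ds <- simulate_dataset(cfg, ann)

write_annotation(ann, file.path(out, "annotation.tsv"))
write_segments(ds$segments, file.path(out, "segments.tsv"))
write_matrix(ds$beta, file.path(out, "beta.tsv"))
write_matrix(ds$expr, file.path(out, "expr.tsv"))
write_probe_map(ds$probe_map_meth, file.path(out, "probe_map_meth.tsv"))
write_probe_map(ds$probe_map_expr, file.path(out, "probe_map_expr.tsv"))
write.table(ds$truth$planted, file.path(out, "truth_planted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$gene_label, file.path(out, "truth_gene_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes on %d autosomes (%d gene-bearing arms)\n",
            nrow(ann), cfg$n_chromosomes, length(gene_arms(ann))))
cat(sprintf("case samples: %d  controls: %d\n",
            length(ds$samples), length(ds$controls)))
cat(sprintf("methylation probes: %d  expression probes: %d\n",
            nrow(ds$beta), nrow(ds$expr)))
cat(sprintf("planted gene sets: %s\n",
            paste(sprintf("%s (%d)", unique(ds$truth$gene_label$label),
                          table(ds$truth$gene_label$label)[
                            unique(ds$truth$gene_label$label)]),
                  collapse = ", ")))
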