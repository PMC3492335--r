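#!/usr/bin/env Rscript
# Stage 7 — hierarchical clustering.
#
# Clusters all 21 samples (cases + controls) on each array platform with
# Spearman-correlation distance and complete linkage, cuts each tree into
# two main groups, and re-clusters the samples on the expression profiles
# of the recurrently selected genes (Euclidean/complete), the heat-map
# companion of the integration stage.

suppressPackageStartupMessages(library(triomics))
out <- "results"
dat <- "results/data"
beta <- read_matrix(file.path(dat, "beta.tsv"))
expr <- read_matrix(file.path(dat, "expr.tsv"))
pm_expr <- read_probe_map(file.path(dat, "probe_map_expr.tsv"))
sel <- read.delim(file.path(out, "selected_genes.tsv"))

trees <- list(expression = hcluster(spearman_distance(expr)),
              methylation = hcluster(spearman_distance(beta)))
labels <- do.call(rbind, lapply(names(trees), function(platform) {
  cut <- cut_tree(trees[[platform]], 2L)
  data.frame(platform = platform, sample = names(cut),
             cluster = unname(cut))
}))
write.table(labels, file.path(out, "cluster_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(as_newick(trees$expression), as_newick(trees$methylation)),
           file.path(out, "dendrograms.nwk"))

for (platform in names(trees)) {
  cut <- cut_tree(trees[[platform]], 2L)
  ctrl <- attr(if (platform == "expression") expr else beta, "controls")
  cat(sprintf("%s: 2-cut cluster sizes %s; controls in cluster(s) %s\n",
              platform, paste(table(cut), collapse = "/"),
              paste(unique(cut[ctrl]), collapse = ",")))
}

# selected-gene expression heat-map clustering (Euclidean/complete)
d_expr <- compute_delta(expr)
probes <- pm_expr$probe_id[pm_expr$gene_id %in% sel$gene_id]
sub <- d_expr[rownames(d_expr) %in% probes, , drop = FALSE]
hc_sel <- hcluster(euclidean_distance(sub))
writeLines(as_newick(hc_sel), file.path(out, "dendrogram_selected.nwk"))
cat(sprintf("selected-gene heat map: %d probes (%d genes) x %d case samples\n",
            nrow(sub), length(unique(sel$gene_id)), ncol(sub)))
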