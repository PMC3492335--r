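#!/usr/bin/env Rscript
# Stage 5 — copy-number frequency versus gene density.
#
# Builds cohort gain- and loss-frequency tracks at the union of all sample
# breakpoints and asks, by Monte Carlo permutation of segment values (1,000
# samples, positions fixed), whether gain frequency is higher than expected
# inside gene-covered bases (and loss frequency lower), genome-wide and
# separately for each of the 39 gene-bearing autosomal arms.

suppressPackageStartupMessages(library(triomics))
seed <- 1L
out <- "results"
dat <- "results/data"
ann <- read_annotation(file.path(dat, "annotation.tsv"))
segments <- read_segments(file.path(dat, "segments.tsv"))

gain_track <- build_frequency_track(segments, "gain")
loss_track <- build_frequency_track(segments, "loss")
g <- permutation_test(gain_track, ann, n_perm = 1000L,
                      alternative = "greater", seed = seed + 101L)
l <- permutation_test(loss_track, ann, n_perm = 1000L,
                      alternative = "less", seed = seed + 102L)
arms_gain <- per_arm_tests(gain_track, ann, n_perm = 1000L,
                           alternative = "greater", seed = seed + 103L)
arms_loss <- per_arm_tests(loss_track, ann, n_perm = 1000L,
                           alternative = "less", seed = seed + 104L)

write.table(data.frame(scope = "genome", channel = c("gain", "loss"),
                       observed = c(g$observed, l$observed),
                       p_value = c(g$p_value, l$p_value)),
            file.path(out, "density_genome.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(channel = "gain", arms_gain),
            file.path(out, "density_arms_gain.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(channel = "loss", arms_loss),
            file.path(out, "density_arms_loss.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fmt_p <- function(p, n) {
  if (p <= 1 / (n + 1)) sprintf("< %.3g", 1 / n) else sprintf("= %.3g", p)
}
cat(sprintf("genome-wide gain vs gene density: mean-in-genes %.3f, p %s\n",
            g$observed, fmt_p(g$p_value, g$n_perm)))
cat(sprintf("genome-wide loss vs gene density: mean-in-genes %.3f, p %s\n",
            l$observed, fmt_p(l$p_value, l$n_perm)))
cat(sprintf("per-arm tests: %d/%d arms significant for gain, %d/%d for loss (p < 0.05)\n",
            attr(arms_gain, "n_significant"), sum(arms_gain$estimable),
            attr(arms_loss, "n_significant"), sum(arms_loss$estimable)))
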