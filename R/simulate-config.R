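#' Configuration for the synthetic three-platform cohort
#'
#' Describes the study design that the generator emulates: a panel of case
#' cell lines profiled on three platforms (segmented DNA copy number,
#' methylation beta values, vst-scale expression), a small set of normal
#' control cultures for the methylation and expression platforms, an
#' autosomal genome with variable gene density, and planted recurrent
#' aberrations with known ground truth.
#'
#' Default sizes mirror the emulated study: 19 case samples, 2 controls and
#' 22 autosomes with 538 genes each (11,836 genes, echoing a shared
#' three-platform universe of ~11.8k autosomal genes). Planted sets cover
#' the four expression-consistent pairs plus the gain/hyper-methylation/
#' under-expression triple, at recurrence levels (7-8 of 19 samples) clearly
#' above the downstream selection threshold of 6.
#'
#' @param n_case_samples,n_control_samples panel sizes.
#' @param n_chromosomes number of autosomes (genome is autosomal only).
#' @param genes_per_chromosome genes simulated per chromosome.
#' @param probes_per_gene_meth,probes_per_gene_expr integer vectors; each
#'   gene's probe count is drawn uniformly from the vector (0 allowed, which
#'   drops the gene from that platform and hence from the shared universe).
#' @param density_bias real in `[0,1]`. 0 gives uniform gene density and
#'   density-independent gain/loss placement; larger values make gene
#'   density vary along chromosomes and bias copy-number gains toward
#'   gene-dense (and losses toward gene-poor) regions. The default 0.6
#'   emulates a cohort with a clear gain/gene-density association.
#' @param centromere_fraction centromere position as a fraction of the
#'   chromosome length.
#' @param acrocentric chromosomes whose p arm carries no genes; the default
#'   five acrocentric autosomes give a 39-arm family for per-arm testing.
#'   Use `character(0)` for genes on all 44 arms.
#' @param p_gain,p_loss baseline per-segment probabilities of a background
#'   gain / loss (gains more common, as in high-grade osteosarcoma panels).
#' @param cn_effect absolute segment mean log-ratio of a gain (loss is the
#'   negative); must clear `cn_gain` by at least two `noise_cn` SDs.
#' @param delta_beta_effect planted methylation shift on the beta scale;
#'   must clear the deltaBeta cut by two beta-scale noise SDs.
#' @param expr_effect planted expression shift (vst units); must clear the
#'   vst-ratio cut by two `noise_expr` SDs.
#' @param cn_expr_coef additive expression effect per copy-number state unit
#'   (+1 gain, -1 loss); couples the platforms the way dosage couples copy
#'   number to expression.
#' @param meth_expr_coef additive expression effect per unit of true
#'   methylation shift (negative: hyper-methylation represses).
#' @param noise_cn,noise_meth,noise_expr platform noise SDs: segment
#'   log-ratio, latent (logit) methylation scale, vst scale.
#' @param planted list of planted aberration sets; each element is a list
#'   with `label`, `channels` (subset of gain/loss/hyper/hypo/over/under,
#'   at most one per platform), and either `n_genes` or explicit `genes`,
#'   plus `n_samples` or explicit `samples` (case-sample indices). A set
#'   may instead give `split`, a list of two channel vectors: each gene's
#'   affected samples are then divided between the two mechanisms (e.g.
#'   over-expression via gain in half the samples and via hypo-methylation
#'   in the other half — the situation the union selection rule targets).
#'   `NULL` plants nothing (a null configuration).
#' @param seed master seed; together with the config it fully determines
#'   every emitted object. Per-platform RNG streams are derived from it.
#' @return a validated list of class `triomics_sim_config`.
#' @export
simulation_config <- function(n_case_samples = 19L,
                              n_control_samples = 2L,
                              n_chromosomes = 22L,
                              genes_per_chromosome = 538L,
                              probes_per_gene_meth = c(1L, 1L, 2L),
                              probes_per_gene_expr = c(1L, 2L),
                              density_bias = 0.6,
                              centromere_fraction = 0.4,
                              acrocentric = c("13", "14", "15", "21", "22"),
                              p_gain = 0.18,
                              p_loss = 0.10,
                              cn_effect = 0.5,
                              delta_beta_effect = 0.55,
                              expr_effect = 2.0,
                              cn_expr_coef = 0.5,
                              meth_expr_coef = -1.0,
                              noise_cn = 0.1,
                              noise_meth = 0.15,
                              noise_expr = 0.3,
                              planted = default_planted_sets(),
                              seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("n_case_samples", "n_chromosomes", "genes_per_chromosome"))
    if (!is_count(cfg[[f]]))
      abort_validation("triomics_config_error", sprintf("%s must be a count >= 1", f))
  if (!is_count(n_control_samples, min = 1L))
    abort_validation("triomics_config_error", "n_control_samples must be >= 1")
  if (n_chromosomes > 22L)
    abort_validation("triomics_config_error", "at most 22 autosomes are supported")
  if (!is.numeric(density_bias) || density_bias < 0 || density_bias > 1)
    abort_validation("triomics_config_error", "density_bias must lie in [0,1]")
  for (f in c("probes_per_gene_meth", "probes_per_gene_expr")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) < 1L || any(v < 0) || any(v != as.integer(v)))
      abort_validation("triomics_config_error",
                       sprintf("%s must be a vector of non-negative integers", f))
  }
  if (!is_count(seed, min = 0L) || seed > 2^31 - 10)
    abort_validation("triomics_config_error", "seed must be an integer in [0, 2^31-10]")
  cfg$acrocentric <- as.character(acrocentric)
  cfg$planted <- validate_planted(planted, cfg)
  structure(cfg, class = "triomics_sim_config")
}

#' Default planted aberration sets
#'
#' The study-design defaults: the four expression-consistent two-way
#' combinations plus the gain/hyper/under triple, planted in 7-8 of 19 case
#' samples (above the recurrence threshold of 6).
#' @return list of planted-set specifications.
#' @export
default_planted_sets <- function() {
  list(
    list(label = "gain+over",         channels = c("gain", "over"),           n_genes = 30L, n_samples = 8L),
    list(label = "hyper+under",       channels = c("hyper", "under"),         n_genes = 30L, n_samples = 8L),
    list(label = "hypo+over",         channels = c("hypo", "over"),           n_genes = 10L, n_samples = 7L),
    list(label = "loss+under",        channels = c("loss", "under"),          n_genes = 10L, n_samples = 7L),
    list(label = "gain+hyper+under",  channels = c("gain", "hyper", "under"), n_genes = 16L, n_samples = 7L),
    list(label = "either+over",       split = list(c("gain", "over"), c("hypo", "over")),
         n_genes = 15L, n_samples = 8L)
  )
}

channel_platform_map <- c(gain = "cn", loss = "cn", hyper = "meth",
                          hypo = "meth", over = "expr", under = "expr")

validate_planted <- function(planted, cfg) {
  if (is.null(planted) || length(planted) == 0L) return(list())
  th <- default_thresholds()
  # Unsatisfiable-configuration guard: every planted effect must clear its
  # calling threshold by at least two noise SDs (beta-scale noise SD is
  # bounded by latent SD times the logistic's maximum slope, 1/4).
  if (cfg$cn_effect - 2 * cfg$noise_cn <= th$cn_gain)
    abort_validation("triomics_unsatisfiable_error",
      "cn_effect does not clear the gain threshold by 2 noise SDs")
  if (cfg$delta_beta_effect - 2 * (cfg$noise_meth / 4) <= th$delta_beta)
    abort_validation("triomics_unsatisfiable_error",
      "delta_beta_effect does not clear the deltaBeta threshold by 2 noise SDs")
  if (cfg$expr_effect - 2 * cfg$noise_expr <= th$vst_ratio)
    abort_validation("triomics_unsatisfiable_error",
      "expr_effect does not clear the vst-ratio threshold by 2 noise SDs")
  lapply(planted, function(p) {
    parts <- if (!is.null(p$split)) p$split else list(p$channels)
    for (ch_set in parts) {
      if (is.null(ch_set) || !all(ch_set %in% names(channel_platform_map)))
        abort_validation("triomics_config_error",
          "planted channels must be drawn from gain/loss/hyper/hypo/over/under")
      if (anyDuplicated(channel_platform_map[ch_set]))
        abort_validation("triomics_config_error",
          "planted set uses two channels from the same platform")
    }
    if (!is.null(p$split) && length(p$split) != 2L)
      abort_validation("triomics_config_error",
        "a split planted set needs exactly two channel vectors")
    if (is.null(p$genes) && !is_count(p$n_genes %||% NULL))
      abort_validation("triomics_config_error",
        "planted set needs n_genes or explicit genes")
    if (is.null(p$samples)) {
      if (!is_count(p$n_samples %||% NULL))
        abort_validation("triomics_config_error",
          "planted set needs n_samples or explicit samples")
      if (p$n_samples > cfg$n_case_samples)
        abort_validation("triomics_config_error",
          "n_samples of a planted set exceeds n_case_samples")
    } else if (any(p$samples < 1L) || any(p$samples > cfg$n_case_samples)) {
      abort_validation("triomics_config_error",
        "explicit planted sample indices out of range")
    }
    p$label <- p$label %||% paste(vapply(parts, paste, "", collapse = "+"),
                                  collapse = "|")
    p
  })
}
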