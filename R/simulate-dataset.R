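#' Simulate the three-platform dataset with planted ground truth
#'
#' Generates, from one master seed, (1) per-case-sample segmented copy
#' number profiles whose breakpoints fall in intergenic gaps, with gains
#' placed preferentially in gene-dense regions when `density_bias > 0`;
#' (2) a probe-level methylation beta matrix (cases + controls) from a
#' latent-normal model passed through the logistic map, so beta stays
#' strictly inside (0,1) and planted shifts are exact on the beta scale at
#' zero noise; (3) a probe-level expression matrix on the vst (log-like)
#' scale coupling additively to copy-number state and methylation shift;
#' and (4) ground-truth tables enumerating every gene/sample/channel.
#'
#' Each platform draws from its own RNG stream derived from the master
#' seed, so changing probe counts on one platform leaves the others
#' byte-identical.
#'
#' @param config a [simulation_config()].
#' @param annotation the [simulate_genome()] output for the same config.
#' @return a list of class `triomics_dataset` with elements `segments`
#'   (data.frame sample/chrom/start/end/value), `beta` and `expr`
#'   (probe-by-sample matrices with `role` and `controls` attributes),
#'   `probe_map_meth` / `probe_map_expr` (probe_id, gene_id), `truth`
#'   (list: `cn_state` character gene-by-case matrix, `meth_shift` and
#'   `expr_shift` numeric gene-by-case matrices, `planted` long
#'   data.frame, `gene_label` per-gene labels), `samples`, `controls`.
#' @export
simulate_dataset <- function(config, annotation) {
  stopifnot(inherits(config, "triomics_sim_config"),
            inherits(annotation, "gene_annotation"))
  genes <- annotation$gene_id
  G <- length(genes)
  cases <- sprintf("case%02d", seq_len(config$n_case_samples))
  ctrls <- sprintf("ctrl%d", seq_len(config$n_control_samples))

  planted <- assign_planted(config, genes)
  seg <- simulate_cn(config, annotation, planted, cases)
  meth <- simulate_meth(config, genes, planted, cases, ctrls)
  expr <- simulate_expr(config, genes, planted, cases, ctrls,
                        seg$state_num, meth$shift)

  planted_long <- planted_table(planted, genes, cases)
  truth <- list(
    cn_state = seg$state_chr,
    meth_shift = meth$shift,
    expr_shift = expr$shift,
    planted = planted_long,
    gene_label = planted$gene_label
  )
  structure(list(segments = seg$segments, beta = meth$beta,
                 expr = expr$values,
                 probe_map_meth = meth$probe_map,
                 probe_map_expr = expr$probe_map,
                 truth = truth, samples = cases, controls = ctrls,
                 config = config),
            class = "triomics_dataset")
}

# ---- planted assignment (stream seed+4) ------------------------------------

assign_planted <- function(config, genes) {
  G <- length(genes)
  n_case <- config$n_case_samples
  ch_names <- names(channel_platform_map)
  ind <- lapply(ch_names, function(ch)
    matrix(FALSE, G, n_case, dimnames = list(genes, NULL)))
  names(ind) <- ch_names
  gene_label <- data.frame(gene_id = character(0), label = character(0))
  if (length(config$planted)) with_seed(config$seed + 4L, {
    taken <- character(0)
    for (p in config$planted) {
      if (!is.null(p$genes)) {
        gset <- p$genes
        if (!all(gset %in% genes))
          abort_validation("triomics_config_error",
                           "planted set names genes absent from the annotation")
      } else {
        avail <- setdiff(genes, taken)
        if (length(avail) < p$n_genes)
          abort_validation("triomics_config_error",
                           "not enough unplanted genes left for planted set")
        gset <- sample(avail, p$n_genes)
      }
      taken <- union(taken, gset)
      for (g in gset) {
        smp <- if (!is.null(p$samples)) as.integer(p$samples)
               else sample.int(n_case, p$n_samples)
        if (is.null(p$split)) {
          for (ch in p$channels) ind[[ch]][g, smp] <- TRUE
        } else {
          # split sets: same downstream consequence (e.g. over-expression)
          # reached through one mechanism in the first half of the affected
          # samples and through the other mechanism in the second half
          half <- ceiling(length(smp) / 2)
          for (ch in p$split[[1]]) ind[[ch]][g, smp[seq_len(half)]] <- TRUE
          for (ch in p$split[[2]])
            ind[[ch]][g, smp[seq.int(half + 1L, length(smp))]] <- TRUE
        }
      }
      gene_label <- rbind(gene_label,
                          data.frame(gene_id = gset, label = p$label))
    }
  })
  c(ind, list(gene_label = gene_label))
}

planted_table <- function(planted, genes, cases) {
  out <- list()
  for (ch in names(channel_platform_map)) {
    hit <- which(planted[[ch]], arr.ind = TRUE)
    if (nrow(hit))
      out[[ch]] <- data.frame(gene_id = genes[hit[, 1]],
                              sample = cases[hit[, 2]], channel = ch)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), sample = character(0),
                      channel = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$sample, res$channel), ]
}

# ---- copy number (stream seed+1) -------------------------------------------

simulate_cn <- function(config, annotation, planted, cases) {
  th <- default_thresholds()
  dens <- attr(annotation, "density")
  lens <- attr(annotation, "chrom_lengths")
  chroms <- names(lens)
  logw <- log(dens$weight)
  sdw <- stats::sd(logw)
  dens$z <- if (is.na(sdw) || sdw == 0) 0 else (logw - mean(logw)) / sdw
  G <- nrow(annotation)
  n_case <- length(cases)
  state_num <- matrix(0L, G, n_case, dimnames = list(annotation$gene_id, NULL))
  with_seed(config$seed + 1L, {
    seg_rows <- vector("list", n_case * length(chroms))
    k <- 0L
    for (si in seq_len(n_case)) {
      for (chrom in chroms) {
        k <- k + 1L
        len <- lens[[chrom]]
        gsel <- annotation$chrom == chrom
        gs <- annotation$start[gsel]
        ge <- annotation$end[gsel]
        gidx <- which(gsel)
        # breakpoints uniform along the chromosome (independent of gene
        # placement, so the density test's null holds under zero bias),
        # snapped out of gene bodies so no gene straddles a breakpoint
        n_bp <- max(3L, round(len / 1.2e6))
        raw <- sort(round(stats::runif(n_bp) * len))
        gi_hit <- findInterval(raw, gs)
        inside <- gi_hit >= 1L & raw < ge[pmax(gi_hit, 1L)]
        raw[inside] <- gs[gi_hit[inside]]
        bp <- sort(unique(c(0, raw, len)))
        S <- length(bp) - 1L
        # density z per segment: mean window z over the segment span
        wz <- dens$z[dens$chrom == chrom]
        win_of <- function(pos) pmin(length(wz), pos %/% 250000L + 1L)
        zseg <- vapply(seq_len(S), function(i) {
          wi <- win_of(bp[i]):win_of(bp[i + 1L] - 1L)
          mean(wz[wi])
        }, numeric(1))
        pg <- stats::plogis(stats::qlogis(config$p_gain) + 2 * config$density_bias * zseg)
        pl <- stats::plogis(stats::qlogis(config$p_loss) - 2 * config$density_bias * zseg)
        u <- stats::runif(S)
        st <- integer(S)            # +1 gain, 0 normal, -1 loss
        st[u < pg] <- 1L
        st[u >= pg & u < pg + pl] <- -1L
        # planted overrides: carve the gene's own interval out of its segment
        pg_idx <- which(planted$gain[gidx, si] | planted$loss[gidx, si])
        if (length(pg_idx)) {
          for (j in pg_idx) {
            want <- if (planted$gain[gidx[j], si]) 1L else -1L
            res <- split_segment(bp, st, gs[j], ge[j], want)
            bp <- res$bp; st <- res$st
          }
          S <- length(st)
        }
        val <- st * config$cn_effect +
          if (config$noise_cn > 0) stats::rnorm(S, 0, config$noise_cn) else 0
        seg_rows[[k]] <- data.frame(sample = cases[si], chrom = chrom,
                                    start = bp[-length(bp)], end = bp[-1],
                                    value = val)
        state_num[gidx, si] <- st[findInterval(gs, bp[-length(bp)])]
      }
    }
    segments <- do.call(rbind, seg_rows)
    rownames(segments) <- NULL
    state_chr <- matrix(c("loss", "normal", "gain")[state_num + 2L],
                        nrow = G, dimnames = dimnames(state_num))
    list(segments = segments, state_num = state_num, state_chr = state_chr)
  })
}

# split the segment covering [gs, ge) at the gene bounds and force its state;
# pieces of old segments keep their state, the gene's own piece takes `want`
split_segment <- function(bp, st, gs, ge, want) {
  new_bp <- sort(unique(c(bp, gs, ge)))
  new_st <- st[findInterval(new_bp[-length(new_bp)], bp[-length(bp)])]
  new_st[findInterval(gs, new_bp[-length(new_bp)])] <- want
  list(bp = new_bp, st = new_st)
}

# ---- methylation (stream seed+2) -------------------------------------------

simulate_meth <- function(config, genes, planted, cases, ctrls) {
  G <- length(genes)
  eff <- config$delta_beta_effect
  with_seed(config$seed + 2L, {
    mu <- stats::rnorm(G, 0, 1.2)
    is_hyper <- rowSums(planted$hyper) > 0
    is_hypo <- rowSums(planted$hypo) > 0
    # planted genes get baselines that leave room for the shift
    mu[is_hyper] <- stats::qlogis(stats::runif(sum(is_hyper), 0.10, 0.30))
    mu[is_hypo] <- stats::qlogis(stats::runif(sum(is_hypo), 0.70, 0.90))
    n_probes <- sample(config$probes_per_gene_meth, G, replace = TRUE)
    probe_gene <- rep.int(seq_len(G), n_probes)
    P <- length(probe_gene)
    lp <- mu[probe_gene] + stats::rnorm(P, 0, 0.15)
    base_beta <- stats::plogis(lp)
    # per-probe latent shifts realising an exact beta-scale shift of +/- eff
    up <- stats::qlogis(pmin(base_beta + eff, 0.985)) - lp
    dn <- stats::qlogis(pmax(base_beta - eff, 0.015)) - lp
    shift_beta <- eff * (planted$hyper - planted$hypo)        # gene x case
    latent_shift <- matrix(0, P, length(cases))
    hy <- planted$hyper[probe_gene, , drop = FALSE]
    ho <- planted$hypo[probe_gene, , drop = FALSE]
    latent_shift[hy] <- rep(up, length(cases))[as.vector(hy)]
    latent_shift[ho] <- rep(dn, length(cases))[as.vector(ho)]
    noise <- function(n) if (config$noise_meth > 0)
      stats::rnorm(n, 0, config$noise_meth) else 0
    case_lat <- lp + latent_shift + noise(P * length(cases))
    ctrl_lat <- matrix(lp, P, length(ctrls)) + noise(P * length(ctrls))
    beta <- stats::plogis(cbind(case_lat, ctrl_lat))
    probe_ids <- sprintf("mp%06d", seq_len(P))
    dimnames(beta) <- list(probe_ids, c(cases, ctrls))
    attr(beta, "role") <- "beta"
    attr(beta, "controls") <- ctrls
    list(beta = beta,
         probe_map = data.frame(probe_id = probe_ids,
                                gene_id = genes[probe_gene]),
         shift = shift_beta)
  })
}

# ---- expression (stream seed+3) --------------------------------------------

simulate_expr <- function(config, genes, planted, cases, ctrls,
                          cn_state_num, meth_shift) {
  G <- length(genes)
  with_seed(config$seed + 3L, {
    b <- stats::rnorm(G, 8, 1.5)
    n_probes <- sample(config$probes_per_gene_expr, G, replace = TRUE)
    probe_gene <- rep.int(seq_len(G), n_probes)
    P <- length(probe_gene)
    pb <- b[probe_gene] + stats::rnorm(P, 0, 0.2)
    shift <- config$cn_expr_coef * cn_state_num +
      config$meth_expr_coef * meth_shift +
      config$expr_effect * (planted$over - planted$under)      # gene x case
    noise <- function(n) if (config$noise_expr > 0)
      stats::rnorm(n, 0, config$noise_expr) else 0
    vals <- cbind(pb + shift[probe_gene, , drop = FALSE] + noise(P * length(cases)),
                  matrix(pb, P, length(ctrls)) + noise(P * length(ctrls)))
    probe_ids <- sprintf("ep%06d", seq_len(P))
    dimnames(vals) <- list(probe_ids, c(cases, ctrls))
    attr(vals, "role") <- "vst"
    attr(vals, "controls") <- ctrls
    list(values = vals,
         probe_map = data.frame(probe_id = probe_ids,
                                gene_id = genes[probe_gene]),
         shift = shift)
  })
}
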