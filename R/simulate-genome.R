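#' Simulate an autosomal gene annotation with variable gene density
#'
#' Builds a genome of `n_chromosomes` autosomes, each divided into fixed
#' 250 kb windows carrying a density weight. With `density_bias = 0` all
#' weights are equal; otherwise weights are a smoothed log-normal field
#' whose amplitude grows with the bias, and genes are allocated to windows
#' multinomially in proportion to the weights, so per-window gene counts
#' correlate with the stored density field. Within a window genes occupy
#' disjoint slots, so intervals never overlap. The centromere sits at a
#' fixed fraction of the chromosome length; acrocentric chromosomes carry
#' genes only on the q arm.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` of class `gene_annotation` with columns
#'   `chrom`, `start`, `end`, `gene_id`, `arm` (0-based half-open
#'   coordinates), and attributes `chrom_lengths`, `centromeres` (named
#'   numeric vectors) and `density` (window-level weight track).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "triomics_sim_config"))
  win_len <- 250000L
  genes_per_window <- 5
  with_seed(config$seed, {
    chroms <- autosomes(config$n_chromosomes)
    ann <- vector("list", length(chroms))
    dens <- vector("list", length(chroms))
    chrom_lengths <- centromeres <- stats::setNames(numeric(length(chroms)), chroms)
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      n_win <- max(8L, ceiling(config$genes_per_chromosome / genes_per_window))
      len <- n_win * win_len
      centro <- round(config$centromere_fraction * len)
      chrom_lengths[chrom] <- len
      centromeres[chrom] <- centro
      if (config$density_bias > 0) {
        # smoothed log-normal density field; moving average of 5 gives the
        # spatial autocorrelation real gene density shows at Mb scale
        z <- stats::rnorm(n_win + 4L)
        z <- stats::filter(z, rep(1 / 5, 5), sides = 2)[3:(n_win + 2L)]
        w <- exp(3 * config$density_bias * as.numeric(z))
      } else {
        z <- stats::rnorm(n_win)  # keep stream alignment across bias settings
        w <- rep(1, n_win)
      }
      win_start <- (seq_len(n_win) - 1L) * win_len
      alloc_w <- w
      if (chrom %in% config$acrocentric) alloc_w[win_start < centro] <- 0
      counts <- as.integer(stats::rmultinom(1L, config$genes_per_chromosome,
                                            alloc_w / sum(alloc_w)))
      # genes in slots within each window, disjoint by construction; gene
      # length is ~20 kb (capped by slot size) so the base-pair coverage of
      # a window grows with its gene count, i.e. with the density field
      rows <- vector("list", n_win)
      for (wi in which(counts > 0L)) {
        k <- counts[wi]
        slot <- win_len / k
        len <- pmin(stats::runif(k, 12000, 26000), 0.8 * slot)
        off <- stats::runif(k) * (slot - len)
        s <- round(win_start[wi] + (seq_len(k) - 1L) * slot + off)
        e <- round(s + len)
        rows[[wi]] <- data.frame(chrom = chrom, start = s, end = e)
      }
      g <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      g <- g[order(g$start), , drop = FALSE]
      mid <- (g$start + g$end) / 2
      g$gene_id <- sprintf("g%s_%04d", chrom, seq_len(nrow(g)))
      g$arm <- ifelse(mid < centro, "p", "q")
      ann[[ci]] <- g[, c("chrom", "start", "end", "gene_id", "arm")]
      dens[[ci]] <- data.frame(chrom = chrom, start = win_start,
                               end = win_start + win_len, weight = w)
    }
    out <- do.call(rbind, ann)
    rownames(out) <- NULL
    structure(out,
              chrom_lengths = chrom_lengths,
              centromeres = centromeres,
              density = do.call(rbind, dens),
              class = c("gene_annotation", "data.frame"))
  })
}

#' Chromosome arms that carry genes
#' @param annotation a `gene_annotation`.
#' @return character vector like `"1p"`, `"1q"`, ... in genome order.
#' @export
gene_arms <- function(annotation) {
  a <- paste0(annotation$chrom, annotation$arm)
  ord <- order(match(annotation$chrom, autosomes()), annotation$arm)
  unique(a[ord])
}
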