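#' Cohort aberration-frequency track from per-sample segments
#'
#' Partitions each chromosome at the union of all samples' segment
#' breakpoints; each resulting elementary segment carries the fraction of
#' samples whose covering segment calls the chosen aberration (mean
#' log-ratio at/above the gain cut, or at/below the loss cut).
#'
#' @param segments per-sample segments (`sample chrom start end value`);
#'   each sample's segments must partition its chromosomes.
#' @param channel `"gain"` or `"loss"`.
#' @param th thresholds.
#' @return data.frame `chrom start end value` of class `frequency_track`
#'   with attributes `channel` and `n_samples`; values in `[0,1]`.
#' @export
build_frequency_track <- function(segments, channel = c("gain", "loss"),
                                  th = default_thresholds()) {
  channel <- match.arg(channel)
  validate_segments(segments)
  samples <- unique(segments$sample)
  out <- list()
  for (chrom in unique(segments$chrom)) {
    seg_c <- segments[segments$chrom == chrom, , drop = FALSE]
    bp <- sort(unique(c(seg_c$start, seg_c$end)))
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    hit <- matrix(FALSE, length(starts), length(samples))
    for (si in seq_along(samples)) {
      ss <- seg_c[seg_c$sample == samples[si], , drop = FALSE]
      ss <- ss[order(ss$start), , drop = FALSE]
      idx <- findInterval(starts, ss$start)
      covered <- idx >= 1L & starts < ss$end[pmax(idx, 1L)]
      v <- rep(NA_real_, length(starts))
      v[covered] <- ss$value[idx[covered]]
      hit[, si] <- !is.na(v) &
        if (channel == "gain") v >= th$cn_gain else v <= th$cn_loss
    }
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               value = rowMeans(hit))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, channel = channel, n_samples = length(samples),
            class = c("frequency_track", "data.frame"))
}

# base pairs of each track segment covered by the flattened gene intervals
gene_coverage_weights <- function(track, genes) {
  w <- numeric(nrow(track))
  for (chrom in unique(track$chrom)) {
    ti <- which(track$chrom == chrom)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!nrow(g)) next
    gr <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    tr <- IRanges::IRanges(track$start[ti] + 1L, track$end[ti])
    ov <- IRanges::findOverlaps(tr, gr)
    if (!length(ov)) next
    iw <- IRanges::width(IRanges::pintersect(
      tr[S4Vectors::queryHits(ov)], gr[S4Vectors::subjectHits(ov)]))
    agg <- rowsum(iw, S4Vectors::queryHits(ov))
    w[ti[as.integer(rownames(agg))]] <- agg[, 1]
  }
  w
}

#' Mean track value inside gene-covered regions
#'
#' The test statistic of the density analysis: the mean of the track's
#' values over the bases covered by genes. Overlapping genes are flattened
#' to a union of covered bases first, so dense loci are not double
#' counted. By default the mean is base-pair weighted; the
#' segment-weighted variant (plain mean over segments that touch a gene)
#' is available since the original definition does not disambiguate.
#'
#' @param track a [build_frequency_track()] result (any `chrom start end
#'   value` data.frame works).
#' @param genes a `gene_annotation`.
#' @param weighting `"bp"` (default) or `"segment"`.
#' @return numeric statistic.
#' @export
mean_in_regions <- function(track, genes, weighting = c("bp", "segment")) {
  weighting <- match.arg(weighting)
  w <- gene_coverage_weights(track, genes)
  if (sum(w) == 0)
    abort_validation("triomics_not_estimable_error",
                     "genes cover zero bases of the track")
  if (weighting == "segment") mean(track$value[w > 0])
  else sum(w * track$value) / sum(w)
}

#' Monte Carlo permutation test of frequency versus gene coverage
#'
#' Null hypothesis: a segment's value and its overlap with genes are
#' uncorrelated. The values are permuted uniformly among the segments
#' (positions and segmentation fixed) and the mean-in-gene-regions
#' statistic recomputed; the p-value uses the add-one estimator
#' p = (1 + #\{permuted >= observed\}) / (n_perm + 1) for alternative
#' `"greater"` (<= for `"less"`), so p is never 0 and a zero-exceedance
#' run at 1,000 permutations reports p < 0.001.
#'
#' @param track frequency (or any segment-value) track.
#' @param genes gene annotation.
#' @param n_perm number of Monte Carlo permutations (default 1000).
#' @param alternative `"greater"` (gains concentrate in gene-covered
#'   regions) or `"less"` (losses avoid them).
#' @param seed RNG seed; identical seed gives an identical p-value.
#' @param weighting passed to [mean_in_regions()].
#' @param scope label stored in the result (`"genome"` or an arm id).
#' @return list of class `permutation_result`: scope, observed, n_perm,
#'   p_value, alternative, seed.
#' @export
permutation_test <- function(track, genes, n_perm = 1000L,
                             alternative = c("greater", "less"),
                             seed = 1L, weighting = c("bp", "segment"),
                             scope = "genome") {
  alternative <- match.arg(alternative)
  weighting <- match.arg(weighting)
  if (nrow(track) < 2L)
    abort_validation("triomics_not_estimable_error",
                     "permutation needs at least two segments in scope")
  stopifnot(is_count(n_perm))
  w <- gene_coverage_weights(track, genes)
  if (sum(w) == 0)
    abort_validation("triomics_not_estimable_error",
                     "genes cover zero bases of the track")
  v <- track$value
  stat <- if (weighting == "bp") {
    W <- sum(w)
    function(val) sum(w * val) / W
  } else {
    inside <- w > 0
    function(val) mean(val[inside])
  }
  observed <- stat(v)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(v[sample.int(length(v))]), numeric(1)))
  exceed <- if (alternative == "greater") sum(perm >= observed)
            else sum(perm <= observed)
  structure(list(scope = scope, observed = observed, n_perm = n_perm,
                 p_value = (1 + exceed) / (n_perm + 1),
                 alternative = alternative, seed = seed),
            class = "permutation_result")
}

#' Per-arm permutation tests
#'
#' Runs [permutation_test()] restricted to each chromosome arm that
#' carries genes: track segments are clipped to the arm (split at the
#' centromere) and only the arm's genes count as covered regions. With the
#' default acrocentric genome preset this is a 39-arm family. Arms with
#' fewer than two segments or no gene coverage are flagged, not tested.
#'
#' @param track frequency track.
#' @param genes a `gene_annotation` with `centromeres` attribute.
#' @param n_perm,alternative,weighting as in [permutation_test()].
#' @param seed master seed; each arm uses a sub-seed derived from it.
#' @return data.frame: arm, observed, p_value, n_segments, estimable;
#'   attribute `n_significant` = number of estimable arms with p < 0.05.
#' @export
per_arm_tests <- function(track, genes, n_perm = 1000L,
                          alternative = c("greater", "less"), seed = 1L,
                          weighting = c("bp", "segment")) {
  alternative <- match.arg(alternative)
  weighting <- match.arg(weighting)
  centro <- attr(genes, "centromeres")
  if (is.null(centro))
    abort_validation("triomics_input_error",
                     "annotation carries no centromere positions")
  arms <- gene_arms(genes)
  rows <- list()
  for (ai in seq_along(arms)) {
    arm <- arms[ai]
    chrom <- sub("[pq]$", "", arm)
    side <- substr(arm, nchar(arm), nchar(arm))
    cpos <- centro[[chrom]]
    tr <- track[track$chrom == chrom, , drop = FALSE]
    # clip segments to the arm, splitting any segment spanning the centromere
    if (side == "p") {
      tr <- tr[tr$start < cpos, , drop = FALSE]
      tr$end <- pmin(tr$end, cpos)
    } else {
      tr <- tr[tr$end > cpos, , drop = FALSE]
      tr$start <- pmax(tr$start, cpos)
    }
    g <- genes[genes$chrom == chrom & genes$arm == side, , drop = FALSE]
    est <- nrow(tr) >= 2L && nrow(g) > 0 &&
      sum(gene_coverage_weights(tr, g)) > 0
    if (est) {
      res <- permutation_test(tr, g, n_perm = n_perm,
                              alternative = alternative,
                              seed = seed + ai, weighting = weighting,
                              scope = arm)
      rows[[arm]] <- data.frame(arm = arm, observed = res$observed,
                                p_value = res$p_value,
                                n_segments = nrow(tr), estimable = TRUE)
    } else {
      rows[[arm]] <- data.frame(arm = arm, observed = NA_real_,
                                p_value = NA_real_, n_segments = nrow(tr),
                                estimable = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_significant") <-
    sum(out$estimable & out$p_value < 0.05, na.rm = TRUE)
  out
}
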