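#' The six aberration channels
#' @return character vector: gain, loss, hyper, hypo, over, under.
#' @export
call_channels <- function() c("gain", "loss", "hyper", "hypo", "over", "under")

#' Gene-by-sample binary aberration calls over six channels
#'
#' @param genes,samples character vectors defining the universe.
#' @param channels named list of logical gene-by-sample matrices, one per
#'   channel in [call_channels()].
#' @param cn_conflict optional logical matrix flagging genes whose
#'   overlapping copy-number segments disagreed (the gene is then listed in
#'   both the gain and loss channel, mirroring the probe inclusion rule).
#' @param cn_state optional character matrix of three-state copy number
#'   (gain/normal/loss), used by the conditional dependency analysis.
#' @return an object of class `call_matrix`.
#' @export
call_matrix <- function(genes, samples, channels,
                        cn_conflict = NULL, cn_state = NULL) {
  stopifnot(all(call_channels() %in% names(channels)))
  for (ch in call_channels()) {
    m <- channels[[ch]]
    stopifnot(is.logical(m), nrow(m) == length(genes),
              ncol(m) == length(samples))
    dimnames(channels[[ch]]) <- list(genes, samples)
  }
  structure(list(genes = genes, samples = samples,
                 channels = channels[call_channels()],
                 cn_conflict = cn_conflict, cn_state = cn_state),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  for (ch in call_channels())
    cat(sprintf("  %-5s %d calls\n", ch, sum(x$channels[[ch]])))
  invisible(x)
}

#' Per-sample, per-channel call counts
#'
#' The content of a per-sample aberration tally: how many genes carry each
#' channel in each sample.
#' @param calls a `call_matrix`.
#' @return data.frame sample x channel counts in long form.
#' @export
call_counts <- function(calls) {
  out <- expand.grid(sample = calls$samples, channel = call_channels(),
                     stringsAsFactors = FALSE)
  out$n_genes <- mapply(function(s, ch) sum(calls$channels[[ch]][, s]),
                        out$sample, out$channel)
  out
}

#' Quantile normalization
#'
#' Forces every column to the identical value multiset (the row-wise mean
#' of the sorted columns) while preserving within-column ranks. Delegates
#' to `limma::normalizeQuantiles` with tie averaging.
#'
#' @param x numeric matrix with at least two columns.
#' @return normalized matrix; `role`/`controls` attributes preserved.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L)
    abort_validation("triomics_input_error",
                     "quantile normalization needs at least two columns")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attr(out, "role") <- attr(x, "role")
  attr(out, "controls") <- attr(x, "controls")
  out
}

#' Per-gene copy-number states from segmented profiles
#'
#' A gene overlapping a segment with mean log-ratio at or above the gain
#' cut is gained; at or below the loss cut, lost (high copy gain merges
#' into gain and homozygous loss into loss, so the two cuts are all that
#' matters). A gene overlapping segments in conflicting states is listed
#' in every state it touches and flagged, mirroring the probe inclusion
#' rule; its three-state assignment takes the state of the segment with
#' the largest overlap.
#'
#' @param segments per-sample segments (`sample chrom start end value`).
#' @param annotation a `gene_annotation`.
#' @param th thresholds from [default_thresholds()].
#' @param missing_chrom what to do with genes on chromosomes absent from a
#'   sample's track: `"skip"` (default; state `NA` with one warning) or
#'   `"error"`.
#' @return list with logical gene-by-sample matrices `gain`, `loss`,
#'   `conflict`, and character matrix `state` (gain/normal/loss, `NA` if
#'   skipped).
#' @export
call_copy_number <- function(segments, annotation, th = default_thresholds(),
                             missing_chrom = c("skip", "error")) {
  missing_chrom <- match.arg(missing_chrom)
  validate_segments(segments)
  samples <- unique(segments$sample)
  genes <- annotation$gene_id
  G <- length(genes)
  dn <- list(genes, samples)
  gain <- loss <- conflict <- matrix(FALSE, G, length(samples), dimnames = dn)
  state <- matrix(NA_character_, G, length(samples), dimnames = dn)
  gr_genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end))
  missing_seen <- character(0)
  for (si in seq_along(samples)) {
    seg <- segments[segments$sample == samples[si], , drop = FALSE]
    absent <- setdiff(unique(annotation$chrom), unique(seg$chrom))
    if (length(absent)) {
      if (missing_chrom == "error")
        abort_validation("triomics_chromosome_error",
          sprintf("sample %s: no segments on chromosome(s) %s",
                  samples[si], paste(absent, collapse = ",")))
      missing_seen <- union(missing_seen, absent)
    }
    gr_seg <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    gi <- S4Vectors::queryHits(hits)
    sj <- S4Vectors::subjectHits(hits)
    v <- seg$value[sj]
    st <- ifelse(v >= th$cn_gain, 1L, ifelse(v <= th$cn_loss, -1L, 0L))
    ov_width <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_genes)[gi], IRanges::ranges(gr_seg)[sj]))
    has_gain <- tapply(st == 1L, gi, any)
    has_loss <- tapply(st == -1L, gi, any)
    idx <- as.integer(names(has_gain))
    gain[idx, si] <- as.logical(has_gain)
    loss[idx, si] <- as.logical(has_loss)
    conflict[idx, si] <- as.logical(has_gain) & as.logical(has_loss)
    # three-state: state of the maximally overlapping segment
    ord <- order(gi, -ov_width)
    first <- !duplicated(gi[ord])
    state[gi[ord][first], si] <-
      c("loss", "normal", "gain")[st[ord][first] + 2L]
    # a non-conflicted gene overlapping gain+normal counts as gain overall
    state[idx[as.logical(has_gain) & !conflict[idx, si]], si] <- "gain"
    state[idx[as.logical(has_loss) & !conflict[idx, si]], si] <- "loss"
  }
  if (length(missing_seen))
    warning(sprintf("genes on chromosome(s) %s skipped: absent from track",
                    paste(missing_seen, collapse = ",")))
  list(gain = gain, loss = loss, conflict = conflict, state = state)
}

#' Case-minus-control-mean delta matrix
#'
#' For methylation the result is deltaBeta (case beta minus mean control
#' beta); for expression it is the vst ratio (case vst value minus mean
#' control vst value — a difference, since vst is log-like).
#'
#' @param x probe-by-sample matrix with a `controls` attribute, or pass
#'   `controls` explicitly.
#' @param controls character vector of control column names.
#' @return probe-by-case matrix with attributes `role` and `controls`.
#' @export
compute_delta <- function(x, controls = attr(x, "controls")) {
  if (is.null(controls) || !length(controls))
    abort_validation("triomics_control_error", "no control columns designated")
  missing <- setdiff(controls, colnames(x))
  if (length(missing))
    abort_validation("triomics_control_error",
      sprintf("control column(s) %s absent from matrix",
              paste(missing, collapse = ",")))
  cases <- setdiff(colnames(x), controls)
  delta <- x[, cases, drop = FALSE] -
    rowMeans(x[, controls, drop = FALSE])
  if (any(!is.finite(delta)))
    abort_validation("triomics_value_error", "non-finite delta values")
  attr(delta, "role") <- attr(x, "role")
  attr(delta, "controls") <- controls
  delta
}

#' Probe-level aberration calls from a delta matrix
#'
#' Strict inequalities exactly as the cuts are printed: a deltaBeta of
#' exactly 0.4 or a vst ratio of exactly 1.0 is not called.
#'
#' @param delta matrix from [compute_delta()] with role `beta` or `vst`.
#' @param th thresholds.
#' @return named list of two logical probe-by-case matrices: `hyper`/`hypo`
#'   for beta input, `over`/`under` for vst input.
#' @export
call_probes <- function(delta, th = default_thresholds()) {
  role <- attr(delta, "role")
  if (is.null(role) || !role %in% c("beta", "vst"))
    abort_validation("triomics_input_error",
      "call_probes needs a delta matrix with role 'beta' or 'vst'")
  cut <- if (role == "beta") th$delta_beta else th$vst_ratio
  pos <- delta > cut
  neg <- delta < -cut
  if (role == "beta") list(hyper = pos, hypo = neg)
  else list(over = pos, under = neg)
}

#' Collapse probe-level calls to gene level
#'
#' A gene carries a channel if any of its probes does; a gene with one
#' hyper-methylated and one hypo-methylated probe therefore carries both
#' channels (each probe's call puts the gene on the corresponding list).
#'
#' @param probe_calls list of logical probe-by-sample matrices (as from
#'   [call_probes()]).
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param genes gene universe for the output rows (defaults to the mapped
#'   genes). Probes absent from the map are excluded with a warning and
#'   counted in the `n_unmapped` attribute.
#' @return list of logical gene-by-sample matrices, same names as input.
#' @export
collapse_to_genes <- function(probe_calls, probe_map, genes = NULL) {
  probes <- rownames(probe_calls[[1]])
  mapped <- probes %in% probe_map$probe_id
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0)
    warning(sprintf("%d unmapped probe(s) excluded from gene collapse",
                    n_unmapped))
  gene_of <- probe_map$gene_id[match(probes, probe_map$probe_id)]
  genes <- genes %||% unique(probe_map$gene_id)
  out <- lapply(probe_calls, function(m) {
    keep <- mapped & (gene_of %in% genes)
    agg <- rowsum((m[keep, , drop = FALSE]) + 0L, gene_of[keep]) > 0L
    res <- matrix(FALSE, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    res[rownames(agg), ] <- agg
    res
  })
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Assemble the full call matrix over the shared gene universe
#'
#' Runs copy-number, methylation and expression calling and restricts to
#' the shared universe: autosomal genes with a copy-number state and at
#' least one probe on each array platform (the analogue of the genes
#' common to all three platforms).
#'
#' @param segments per-sample copy-number segments (case samples).
#' @param beta probe-by-sample beta matrix with `controls` attribute.
#' @param expr probe-by-sample vst matrix with `controls` attribute;
#'   assumed already variance-stabilized and quantile-normalized (apply
#'   [quantile_normalize()] first otherwise).
#' @param probe_map_meth,probe_map_expr probe-to-gene maps.
#' @param annotation gene annotation.
#' @param th thresholds.
#' @return a [call_matrix()] with `cn_state` and `cn_conflict` filled in.
#' @export
build_call_matrix <- function(segments, beta, expr, probe_map_meth,
                              probe_map_expr, annotation,
                              th = default_thresholds()) {
  cn <- call_copy_number(segments, annotation, th)
  samples <- colnames(cn$gain)
  d_beta <- compute_delta(beta)
  d_expr <- compute_delta(expr)
  universe <- intersect(
    annotation$gene_id[annotation$gene_id %in% rownames(cn$state)[
      rowSums(!is.na(cn$state)) == ncol(cn$state)]],
    intersect(unique(probe_map_meth$gene_id), unique(probe_map_expr$gene_id)))
  universe <- annotation$gene_id[annotation$gene_id %in% universe]
  meth_calls <- collapse_to_genes(call_probes(d_beta, th), probe_map_meth,
                                  genes = universe)
  expr_calls <- collapse_to_genes(call_probes(d_expr, th), probe_map_expr,
                                  genes = universe)
  keep_cases <- intersect(samples, colnames(meth_calls$hyper))
  channels <- list(
    gain = cn$gain[universe, keep_cases, drop = FALSE],
    loss = cn$loss[universe, keep_cases, drop = FALSE],
    hyper = meth_calls$hyper[universe, keep_cases, drop = FALSE],
    hypo = meth_calls$hypo[universe, keep_cases, drop = FALSE],
    over = expr_calls$over[universe, keep_cases, drop = FALSE],
    under = expr_calls$under[universe, keep_cases, drop = FALSE])
  call_matrix(universe, keep_cases, channels,
              cn_conflict = cn$conflict[universe, keep_cases, drop = FALSE],
              cn_state = cn$state[universe, keep_cases, drop = FALSE])
}
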