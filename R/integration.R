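#' Enumerate cross-platform aberration combinations
#'
#' With two aberration types per platform (gain/loss, hyper/hypo,
#' over/under) there are exactly 12 two-way combinations (one channel from
#' each of two platforms) and 8 three-way combinations (one channel from
#' each platform). Order is deterministic: two-way blocks cn x meth,
#' cn x expr, meth x expr, then the three-way block, each in fixed channel
#' order.
#'
#' @return data.frame with columns `label` (e.g. `"gain+over"`), `n_way`,
#'   and `cn`, `meth`, `expr` (the channel drawn from each platform, `NA`
#'   when the platform is not part of the combination).
#' @export
enumerate_combos <- function() {
  cn <- c("gain", "loss"); meth <- c("hyper", "hypo"); expr <- c("over", "under")
  two <- rbind(
    expand.grid(cn = cn, meth = meth, expr = NA_character_,
                stringsAsFactors = FALSE),
    expand.grid(cn = cn, meth = NA_character_, expr = expr,
                stringsAsFactors = FALSE),
    expand.grid(cn = NA_character_, meth = meth, expr = expr,
                stringsAsFactors = FALSE))
  three <- expand.grid(cn = cn, meth = meth, expr = expr,
                       stringsAsFactors = FALSE)
  out <- rbind(cbind(two, n_way = 2L), cbind(three, n_way = 3L))
  out$label <- apply(out[, c("cn", "meth", "expr")], 1,
                     function(r) paste(r[!is.na(r)], collapse = "+"))
  rownames(out) <- NULL
  out[, c("label", "n_way", "cn", "meth", "expr")]
}

combo_channels <- function(combo_row) {
  ch <- unlist(combo_row[c("cn", "meth", "expr")])
  as.character(ch[!is.na(ch)])
}

#' The four expression-consistent two-way combinations
#'
#' Gain with over-expression, hypo-methylation with over-expression, loss
#' with under-expression and hyper-methylation with under-expression: the
#' pairs in which the copy-number or methylation aberration is consistent
#' with the direction of the expression change.
#' @return character vector of four combination labels.
#' @export
expression_consistent_pairs <- function() {
  c("gain+over", "hypo+over", "loss+under", "hyper+under")
}

#' Count per-gene recurrence of every combination across samples
#'
#' For each gene and each of the 20 combinations, the number of samples in
#' which the gene carries all channels of the combination simultaneously;
#' single-channel recurrence is included for per-data-type curves.
#'
#' @param calls a [call_matrix()] over the shared universe.
#' @return object of class `recurrence_table`: list with `counts` (genes x
#'   combination integer matrix, columns named by label), `combos`, and
#'   `n_samples`.
#' @export
recurrence <- function(calls) {
  stopifnot(inherits(calls, "call_matrix"))
  if (!length(calls$genes))
    abort_validation("triomics_input_error", "empty gene universe")
  combos <- enumerate_combos()
  counts <- matrix(0L, length(calls$genes),
                   nrow(combos) + length(call_channels()),
                   dimnames = list(calls$genes,
                                   c(combos$label, call_channels())))
  for (i in seq_len(nrow(combos))) {
    ch <- combo_channels(combos[i, ])
    joint <- Reduce(`&`, calls$channels[ch])
    counts[, combos$label[i]] <- as.integer(rowSums(joint))
  }
  for (ch in call_channels())
    counts[, ch] <- as.integer(rowSums(calls$channels[[ch]]))
  structure(list(counts = counts, combos = combos,
                 n_samples = length(calls$samples)),
            class = "recurrence_table")
}

#' Recurrence curve: genes with count >= k, per combination
#'
#' @param table a [recurrence()] result.
#' @return data.frame `combo`, `k`, `n_genes` for k = 1..n_samples;
#'   monotone non-increasing in `k` within each combination.
#' @export
recurrence_curve <- function(table) {
  stopifnot(inherits(table, "recurrence_table"))
  ks <- seq_len(table$n_samples)
  out <- expand.grid(combo = colnames(table$counts), k = ks,
                     stringsAsFactors = FALSE)
  out$n_genes <- mapply(function(cc, k) sum(table$counts[, cc] >= k),
                        out$combo, out$k)
  out[order(match(out$combo, colnames(table$counts)), out$k), ]
}

#' Select recurrently altered genes by two-way combination
#'
#' Genes whose recurrence count reaches `k` ("six or more" at the default)
#' in any of the chosen combinations, annotated with every qualifying
#' combination and its count (not just the first found).
#'
#' @param table a [recurrence()] result.
#' @param combos combination labels to consider; default the four
#'   expression-consistent pairs.
#' @param k recurrence threshold (default 6, i.e. 6/19 > 30% at the
#'   default panel size; strict integer semantics, count >= k).
#' @return data.frame `gene_id`, `combo`, `count` (one row per qualifying
#'   gene x combination).
#' @export
select_recurrent <- function(table, combos = expression_consistent_pairs(),
                             k = 6L) {
  stopifnot(inherits(table, "recurrence_table"), is_count(k))
  rows <- lapply(combos, function(cc) {
    hit <- which(table$counts[, cc] >= k)
    if (!length(hit)) return(NULL)
    data.frame(gene_id = rownames(table$counts)[hit], combo = cc,
               count = as.integer(table$counts[hit, cc]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(0), combo = character(0),
                      count = integer(0)))
  out[order(out$gene_id, out$combo), ]
}

#' Select additional genes via the either-mechanism union rule
#'
#' Copy-number change and methylation change can be alternative mechanisms
#' for the same expression change, so per sample the indicators
#' over-expressed AND (gained OR hypo-methylated), and under-expressed AND
#' (lost OR hyper-methylated), are counted; genes reaching `k` samples on
#' either indicator qualify. Genes already selected by the plain pairwise
#' rule are removed — the result is the *additional* genes the union rule
#' contributes.
#'
#' @param calls a [call_matrix()].
#' @param k recurrence threshold (default 6).
#' @param exclude gene ids to drop (defaults to the [select_recurrent()]
#'   selection at the same `k`).
#' @return data.frame `gene_id`, `combo` (`"union_over"`/`"union_under"`),
#'   `count`.
#' @export
select_union <- function(calls, k = 6L,
                         exclude = unique(select_recurrent(recurrence(calls),
                                                           k = k)$gene_id)) {
  stopifnot(inherits(calls, "call_matrix"), is_count(k))
  ch <- calls$channels
  up <- rowSums(ch$over & (ch$gain | ch$hypo))
  dn <- rowSums(ch$under & (ch$loss | ch$hyper))
  rows <- list(
    data.frame(gene_id = calls$genes[up >= k],
               combo = rep("union_over", sum(up >= k)),
               count = as.integer(up[up >= k])),
    data.frame(gene_id = calls$genes[dn >= k],
               combo = rep("union_under", sum(dn >= k)),
               count = as.integer(dn[dn >= k])))
  out <- do.call(rbind, rows)
  out <- out[!out$gene_id %in% exclude, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}
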