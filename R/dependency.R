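#' 2x2 contingency table of two aberration channels within one sample
#'
#' Cross-tabulates the binary indicators of two channels from different
#' platforms over the shared gene universe: a = both, b = A only, c = B
#' only, d = neither; a+b+c+d equals the universe size.
#'
#' @param calls a [call_matrix()].
#' @param sample sample name.
#' @param channel_a,channel_b channels from different platforms.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
make_table <- function(calls, sample, channel_a, channel_b) {
  stopifnot(inherits(calls, "call_matrix"))
  if (channel_platform_map[[channel_a]] == channel_platform_map[[channel_b]])
    abort_validation("triomics_input_error",
      sprintf("channels %s and %s come from the same platform",
              channel_a, channel_b))
  A <- calls$channels[[channel_a]][, sample]
  B <- calls$channels[[channel_b]][, sample]
  c(a = sum(A & B), b = sum(A & !B), c = sum(!A & B), d = sum(!A & !B))
}

#' Odds ratio of a 2x2 table
#'
#' (a d)/(b c); an odds ratio above 1 means positive association between
#' the two aberrations, below 1 negative, 1 none. With the default Haldane
#' policy 0.5 is added to every cell whenever any cell is zero; with
#' `policy = "none"` a zero cell yields `Inf`/`NaN` flagged via the
#' `infinite` attribute.
#'
#' @param t table from [make_table()] (or any numeric `c(a,b,c,d)`).
#' @param zero_cell_policy `"haldane"` (default) or `"none"`.
#' @return numeric odds ratio, attribute `infinite` set when policy
#'   `"none"` met a zero cell.
#' @export
odds_ratio <- function(t, zero_cell_policy = c("haldane", "none")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  t <- as.numeric(t)
  stopifnot(length(t) == 4L, all(t >= 0))
  if (any(t == 0) && zero_cell_policy == "haldane") t <- t + 0.5
  or <- (t[1] * t[4]) / (t[2] * t[3])
  if (!is.finite(or)) attr(or, "infinite") <- TRUE
  or
}

#' Pearson chi-square test of a 2x2 table
#'
#' One degree of freedom, no continuity correction by default (Yates
#' available via `correct = TRUE`). A degenerate margin (an all-zero row
#' or column) is not testable: statistic 0, p 1, `degenerate` flag set.
#'
#' @param t numeric `c(a,b,c,d)`.
#' @param correct apply Yates continuity correction.
#' @return list `statistic`, `p.value`, `degenerate`.
#' @export
chi_square_p <- function(t, correct = FALSE) {
  t <- as.numeric(t)
  stopifnot(length(t) == 4L, all(t >= 0))
  m <- matrix(t, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p.value = unname(res$p.value),
       degenerate = FALSE)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (min(1, m p)) or Benjamini-Hochberg step-up. The family is
#' whatever vector the caller passes: in the two-way dependency analysis
#' it is the 12 combinations within one sample, in the conditional
#' analysis the strata-by-states tests within one sample.
#'
#' @param p vector of p-values in `[0,1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p))
    abort_validation("triomics_input_error", "empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort_validation("triomics_value_error", "p-values outside [0,1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Per-sample dependency analysis over the 12 two-way combinations
#'
#' For every sample and every two-way cross-platform combination:
#' the 2x2 contingency table over the gene universe, the odds ratio, the
#' chi-square p-value, and the p-value adjusted within the sample's
#' 12-combination family.
#'
#' @param calls a [call_matrix()].
#' @param method adjustment method, default `"bh"` (the method displayed
#'   for significance in the dependency heat maps; `"bonferroni"` as
#'   stated in the running text is also available). Recorded in the
#'   output.
#' @param zero_cell_policy passed to [odds_ratio()].
#' @param correct Yates correction for the chi-square tests.
#' @return data.frame: sample, combo, a, b, c, d, odds_ratio, p,
#'   p_adj, method, degenerate.
#' @export
dependency_analysis <- function(calls, method = c("bh", "bonferroni"),
                                zero_cell_policy = "haldane",
                                correct = FALSE) {
  method <- match.arg(method)
  combos <- enumerate_combos()
  combos <- combos[combos$n_way == 2L, ]
  rows <- list()
  for (s in calls$samples) {
    sub <- lapply(seq_len(nrow(combos)), function(i) {
      ch <- combo_channels(combos[i, ])
      t <- make_table(calls, s, ch[1], ch[2])
      chi <- chi_square_p(t, correct = correct)
      data.frame(sample = s, combo = combos$label[i],
                 a = t[["a"]], b = t[["b"]], c = t[["c"]], d = t[["d"]],
                 odds_ratio = as.numeric(odds_ratio(t, zero_cell_policy)),
                 p = chi$p.value, degenerate = chi$degenerate)
    })
    sub <- do.call(rbind, sub)
    sub$p_adj <- adjust_pvalues(sub$p, method)
    rows[[s]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$method <- method
  out
}

#' Dependencies of methylation and expression conditioned on copy number
#'
#' Genes are divided into three copy-number states (gain, normal, loss —
#' from the three-state assignment carried by the call matrix) and three
#' expression states (over-expressed, normal, under-expressed). Within
#' each copy-number stratum of each sample, hyper-methylation is
#' cross-tabulated against each expression state (that state versus not
#' that state among the stratum's genes), giving odds ratio and corrected
#' chi-square p per stratum/state; the adjustment family is the sample's
#' stratum-by-state tests. Strata with no genes, or tables with a
#' degenerate margin, are flagged not estimable.
#'
#' @param calls a [call_matrix()] whose `cn_state` slot is filled (as from
#'   [build_call_matrix()]).
#' @param method,zero_cell_policy,correct as in [dependency_analysis()].
#' @return data.frame: sample, cn_stratum, expr_state, a, b, c, d,
#'   odds_ratio, p, p_adj, method, estimable.
#' @export
conditional_dependency <- function(calls, method = c("bh", "bonferroni"),
                                   zero_cell_policy = "haldane",
                                   correct = FALSE) {
  method <- match.arg(method)
  if (is.null(calls$cn_state))
    abort_validation("triomics_input_error",
                     "call matrix carries no three-state copy number")
  strata <- c("gain", "normal", "loss")
  estates <- c("over", "normal", "under")
  rows <- list()
  for (s in calls$samples) {
    st <- calls$cn_state[, s]
    hyper <- calls$channels$hyper[, s]
    over <- calls$channels$over[, s]
    under <- calls$channels$under[, s]
    e_ind <- list(over = over, normal = !over & !under, under = under)
    sub <- list()
    for (cs in strata) {
      in_stratum <- !is.na(st) & st == cs
      for (es in estates) {
        if (!any(in_stratum)) {
          sub[[paste(cs, es)]] <- data.frame(
            sample = s, cn_stratum = cs, expr_state = es,
            a = 0L, b = 0L, c = 0L, d = 0L,
            odds_ratio = NA_real_, p = NA_real_, estimable = FALSE)
          next
        }
        A <- hyper[in_stratum]
        B <- e_ind[[es]][in_stratum]
        t <- c(a = sum(A & B), b = sum(A & !B), c = sum(!A & B),
               d = sum(!A & !B))
        chi <- chi_square_p(t, correct = correct)
        sub[[paste(cs, es)]] <- data.frame(
          sample = s, cn_stratum = cs, expr_state = es,
          a = t[["a"]], b = t[["b"]], c = t[["c"]], d = t[["d"]],
          odds_ratio = as.numeric(odds_ratio(t, zero_cell_policy)),
          p = chi$p.value, estimable = !chi$degenerate)
      }
    }
    sub <- do.call(rbind, sub)
    sub$p_adj <- NA_real_
    ok <- !is.na(sub$p)
    if (any(ok)) sub$p_adj[ok] <- adjust_pvalues(sub$p[ok], method)
    rows[[s]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$method <- method
  out
}
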