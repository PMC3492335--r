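#' Beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the log ratio of methylated to
#' unmethylated intensity implied by the beta (methylated fraction)
#' definition. Beta is clamped to `[epsilon, 1 - epsilon]` first so the
#' transform stays finite; it is strictly increasing in beta, so the sign
#' of a deltaBeta always agrees with the sign of the corresponding delta-M.
#'
#' @param beta matrix (or vector) of beta values in `[0,1]`.
#' @param epsilon clamp margin in (0, 0.5).
#' @return matrix of M-values with role attribute `mvalue`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    abort_validation("triomics_value_error", "beta values outside [0,1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attr(m, "role") <- "mvalue"
  attr(m, "controls") <- attr(beta, "controls")
  m
}

#' Row-wise two-sample t-tests, case group versus control group
#'
#' Plain (unmoderated) two-sample t-tests per probe: pooled-variance by
#' default, Welch optionally. A minimum-variance floor guards probes whose
#' tiny control group (n = 2 in the emulated design) makes the variance
#' estimate degenerate. Probes with zero variance in both groups and zero
#' mean difference get t = 0, p = 1 and a flag.
#'
#' @param case,control numeric matrices with identical rows (probes),
#'   columns are samples; at least two columns each.
#' @param var `"pooled"` or `"welch"`.
#' @param var_floor lower bound applied to each group variance.
#' @return data.frame: id, mean_case, mean_control, diff, t, df, p, flag.
#' @export
two_group_ttest <- function(case, control, var = c("pooled", "welch"),
                            var_floor = 0) {
  var <- match.arg(var)
  if (ncol(case) < 2L || ncol(control) < 2L)
    abort_validation("triomics_input_error",
                     "both groups need at least two columns")
  stopifnot(nrow(case) == nrow(control))
  n1 <- ncol(case); n2 <- ncol(control)
  m1 <- rowMeans(case); m2 <- rowMeans(control)
  v1 <- pmax(apply(case, 1, stats::var), var_floor)
  v2 <- pmax(apply(control, 1, stats::var), var_floor)
  d <- m1 - m2
  if (var == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  flag <- se == 0
  t[flag & d == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[flag & d == 0] <- 1
  data.frame(id = rownames(case) %||% as.character(seq_along(d)),
             mean_case = m1, mean_control = m2, diff = d,
             t = t, df = df, p = p, flag = flag, row.names = NULL)
}

#' Filter differential results by adjusted p and fold change
#'
#' A probe passes when its Benjamini-Hochberg-adjusted p-value is below
#' `alpha` AND its absolute fold change (group mean difference on the
#' already log-like M or vst scale) exceeds `fc_cut` — the conventional
#' cuts are 6 for methylation M-values and 0.5 for vst expression. When a
#' probe map is given, probes are collapsed to genes by the inclusion
#' rule: a gene passes if any of its probes does, annotated with the
#' direction(s) of its passing probes.
#'
#' @param results data.frame from [two_group_ttest()].
#' @param alpha adjusted-p cut (default 0.05).
#' @param fc_cut absolute fold-change cut on the test scale.
#' @param probe_map optional `probe_id`/`gene_id` map for gene-level
#'   collapse.
#' @return `results` with `p_adj` and `pass` columns; when `probe_map` is
#'   given, attribute `genes`: data.frame gene_id, direction, n_probes.
#' @export
filter_differential <- function(results, alpha = 0.05, fc_cut,
                                probe_map = NULL) {
  stopifnot(is.numeric(fc_cut), fc_cut > 0)
  results$p_adj <- adjust_pvalues(results$p, "bh")
  results$pass <- results$p_adj < alpha & abs(results$diff) > fc_cut
  if (!is.null(probe_map)) {
    hit <- results[results$pass, , drop = FALSE]
    gene <- probe_map$gene_id[match(hit$id, probe_map$probe_id)]
    keep <- !is.na(gene)
    if (any(keep)) {
      dirs <- ifelse(hit$diff[keep] > 0, "up", "down")
      tab <- stats::aggregate(
        list(direction = dirs, n_probes = rep(1L, sum(keep))),
        by = list(gene_id = gene[keep]),
        FUN = function(x) if (is.character(x))
          paste(sort(unique(x)), collapse = "+") else length(x))
      tab$n_probes <- as.integer(tab$n_probes)
      attr(results, "genes") <- tab
    } else {
      attr(results, "genes") <- data.frame(gene_id = character(0),
                                           direction = character(0),
                                           n_probes = integer(0))
    }
  }
  results
}
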