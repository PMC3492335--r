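#' Aberration-calling thresholds
#'
#' The calling thresholds used throughout the pipeline, on the scales of the
#' respective platforms:
#'
#' * copy number (segment mean log-ratio): `cn_high_gain` (0.6), `cn_gain`
#'   (0.2), `cn_loss` (-0.2), `cn_homozygous_loss` (-1.0). High copy gain is
#'   merged into gain and homozygous loss into loss when calling, so the
#'   effective per-gene states are gain / normal / loss with cuts at
#'   `cn_gain` and `cn_loss` (non-strict: a segment exactly at the cut is
#'   called).
#' * methylation: `delta_beta` (0.4), applied strictly to the difference
#'   between a case beta value and the mean control beta value
#'   (deltaBeta > 0.4 hyper-methylated, < -0.4 hypo-methylated).
#' * expression: `vst_ratio` (1.0), applied strictly to the difference
#'   between a case vst value and the mean control vst value
#'   (> 1 over-expressed, < -1 under-expressed). The vst scale is log-like,
#'   so this difference is a log fold change; a literal ratio could never be
#'   negative as the lower cut requires.
#'
#' @param cn_high_gain,cn_gain,cn_loss,cn_homozygous_loss copy-number cuts
#'   (log-ratio units).
#' @param delta_beta methylation cut, in (0,1).
#' @param vst_ratio expression cut, > 0.
#' @return a named list of class `triomics_thresholds`.
#' @export
default_thresholds <- function(cn_high_gain = 0.6, cn_gain = 0.2,
                               cn_loss = -0.2, cn_homozygous_loss = -1.0,
                               delta_beta = 0.4, vst_ratio = 1.0) {
  th <- list(cn_high_gain = cn_high_gain, cn_gain = cn_gain,
             cn_loss = cn_loss, cn_homozygous_loss = cn_homozygous_loss,
             delta_beta = delta_beta, vst_ratio = vst_ratio)
  if (!(th$cn_high_gain > th$cn_gain && th$cn_gain > 0 &&
        0 > th$cn_loss && th$cn_loss > th$cn_homozygous_loss))
    abort_validation("triomics_threshold_error",
      "copy-number thresholds must satisfy high_gain > gain > 0 > loss > homozygous_loss")
  if (!(th$delta_beta > 0 && th$delta_beta < 1))
    abort_validation("triomics_threshold_error", "delta_beta must lie in (0,1)")
  if (!(th$vst_ratio > 0))
    abort_validation("triomics_threshold_error", "vst_ratio must be positive")
  structure(th, class = "triomics_thresholds")
}
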