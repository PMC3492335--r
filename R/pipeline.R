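#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed for the synthetic cohort and all Monte Carlo.
#' @param sim list of overrides passed to [simulation_config()].
#' @param k recurrence threshold.
#' @param method multiple-testing method (`"bh"` or `"bonferroni"`).
#' @param n_perm Monte Carlo permutations for the density tests.
#' @param weighting statistic weighting for the density tests.
#' @param stages character vector of stages to run, in fixed order:
#'   simulate, call, integrate, depend, density, diff, cluster.
#' @return named list of class `triomics_pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "triomics_run", seed = 1L,
                            sim = list(), k = 6L, method = "bh",
                            n_perm = 1000L, weighting = "bp",
                            stages = c("simulate", "call", "integrate",
                                       "depend", "density", "diff",
                                       "cluster")) {
  structure(as.list(environment()), class = "triomics_pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `triomics_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the integrative pipeline end to end
#'
#' Executes, in the analysis order: synthetic-cohort simulation (optional
#' — supply `data` to analyse an existing dataset), aberration calling,
#' combination recurrence and gene selection, per-sample dependency
#' statistics (two-way and copy-number-conditioned), the gain/loss
#' density permutation tests (genome-wide and per arm), differential
#' methylation/expression, and hierarchical clustering. All stage outputs
#' are written as TSV under `config$out_dir` and a JSON manifest records
#' seeds, stages run, row counts and file checksums; identical
#' configuration yields identical outputs.
#'
#' @param config a [pipeline_config()] (or a YAML path readable by
#'   [read_pipeline_config()]).
#' @param data optional `triomics_dataset`; skips simulation.
#' @return the manifest, invisibly a list with all in-memory stage
#'   results (`dataset`, `calls`, `recurrence`, `selected`, `union`,
#'   `dependency`, `conditional`, `density`, `differential`, `clusters`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "triomics_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  res <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "done", seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  on <- function(s) s %in% config$stages

  if (is.null(data) && on("simulate")) {
    data <- t_stage("simulate", {
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(list(seed = config$seed),
                                           config$sim))
      ann <- simulate_genome(sim_cfg)
      ds <- simulate_dataset(sim_cfg, ann)
      ds$annotation <- ann
      write_annotation(ann, file.path(config$out_dir, "annotation.tsv"))
      write_segments(ds$segments, file.path(config$out_dir, "segments.tsv"))
      write_matrix(ds$beta, file.path(config$out_dir, "beta.tsv"))
      write_matrix(ds$expr, file.path(config$out_dir, "expr.tsv"))
      write_probe_map(ds$probe_map_meth,
                      file.path(config$out_dir, "probe_map_meth.tsv"))
      write_probe_map(ds$probe_map_expr,
                      file.path(config$out_dir, "probe_map_expr.tsv"))
      write_stage_tsv(ds$truth$planted, config$out_dir, "truth_planted.tsv")
      ds
    })
  }
  if (is.null(data))
    abort_validation("triomics_input_error",
                     "no dataset: enable the simulate stage or pass data")
  res$dataset <- data
  ann <- data$annotation

  if (on("call")) {
    res$calls <- t_stage("call", {
      calls <- build_call_matrix(data$segments, data$beta, data$expr,
                                 data$probe_map_meth, data$probe_map_expr,
                                 ann)
      write_calls(calls, file.path(config$out_dir, "calls.tsv"))
      write_stage_tsv(call_counts(calls), config$out_dir, "call_counts.tsv")
      calls
    })
  }
  if (on("integrate") && !is.null(res$calls)) {
    t_stage("integrate", {
      res$recurrence <- recurrence(res$calls)
      res$selected <- select_recurrent(res$recurrence, k = config$k)
      res$union <- select_union(res$calls, k = config$k,
                                 exclude = unique(res$selected$gene_id))
      write_stage_tsv(recurrence_curve(res$recurrence), config$out_dir,
                      "recurrence_curve.tsv")
      write_stage_tsv(res$selected, config$out_dir, "selected_genes.tsv")
      write_stage_tsv(res$union, config$out_dir, "selected_union.tsv")
    })
  }
  if (on("depend") && !is.null(res$calls)) {
    t_stage("depend", {
      res$dependency <- dependency_analysis(res$calls, method = config$method)
      res$conditional <- conditional_dependency(res$calls,
                                                 method = config$method)
      write_stage_tsv(res$dependency, config$out_dir, "dependency.tsv")
      write_stage_tsv(res$conditional, config$out_dir,
                      "dependency_conditional.tsv")
    })
  }
  if (on("density")) {
    t_stage("density", {
      gain_track <- build_frequency_track(data$segments, "gain")
      loss_track <- build_frequency_track(data$segments, "loss")
      g_res <- permutation_test(gain_track, ann, n_perm = config$n_perm,
                                alternative = "greater",
                                seed = config$seed + 101L,
                                weighting = config$weighting)
      l_res <- permutation_test(loss_track, ann, n_perm = config$n_perm,
                                alternative = "less",
                                seed = config$seed + 102L,
                                weighting = config$weighting)
      arms_gain <- per_arm_tests(gain_track, ann, n_perm = config$n_perm,
                                 alternative = "greater",
                                 seed = config$seed + 103L,
                                 weighting = config$weighting)
      arms_loss <- per_arm_tests(loss_track, ann, n_perm = config$n_perm,
                                 alternative = "less",
                                 seed = config$seed + 104L,
                                 weighting = config$weighting)
      res$density <- list(gain = g_res, loss = l_res,
                           arms_gain = arms_gain, arms_loss = arms_loss)
      genome_df <- data.frame(
        scope = "genome", channel = c("gain", "loss"),
        observed = c(g_res$observed, l_res$observed),
        p_value = c(g_res$p_value, l_res$p_value))
      write_stage_tsv(genome_df, config$out_dir, "density_genome.tsv")
      write_stage_tsv(cbind(channel = "gain", arms_gain), config$out_dir,
                      "density_arms_gain.tsv")
      write_stage_tsv(cbind(channel = "loss", arms_loss), config$out_dir,
                      "density_arms_loss.tsv")
    })
  }
  if (on("diff")) {
    t_stage("diff", {
      m <- beta_to_m(data$beta)
      ctrls <- attr(data$beta, "controls")
      cases <- setdiff(colnames(data$beta), ctrls)
      tt_m <- two_group_ttest(m[, cases, drop = FALSE],
                              m[, ctrls, drop = FALSE])
      diff_m <- filter_differential(tt_m, fc_cut = 6,
                                    probe_map = data$probe_map_meth)
      ctrl_e <- attr(data$expr, "controls")
      case_e <- setdiff(colnames(data$expr), ctrl_e)
      tt_e <- two_group_ttest(data$expr[, case_e, drop = FALSE],
                              data$expr[, ctrl_e, drop = FALSE])
      diff_e <- filter_differential(tt_e, fc_cut = 0.5,
                                    probe_map = data$probe_map_expr)
      res$differential <- list(meth = diff_m, expr = diff_e)
      write_stage_tsv(diff_m, config$out_dir, "differential_meth.tsv")
      write_stage_tsv(diff_e, config$out_dir, "differential_expr.tsv")
      write_stage_tsv(attr(diff_m, "genes"), config$out_dir,
                      "differential_meth_genes.tsv")
      write_stage_tsv(attr(diff_e, "genes"), config$out_dir,
                      "differential_expr_genes.tsv")
    })
  }
  if (on("cluster")) {
    t_stage("cluster", {
      hc_expr <- hcluster(spearman_distance(data$expr))
      hc_beta <- hcluster(spearman_distance(data$beta))
      res$clusters <- list(expr = hc_expr, beta = hc_beta,
                            cut_expr = cut_tree(hc_expr, 2L))
      labels <- data.frame(sample = names(res$clusters$cut_expr),
                           cluster = unname(res$clusters$cut_expr))
      write_stage_tsv(labels, config$out_dir, "cluster_labels_expr.tsv")
    })
  }
  skipped <- setdiff(c("simulate", "call", "integrate", "depend", "density",
                       "diff", "cluster"), names(manifest$stages))
  for (s in skipped) manifest$stages[[s]] <- list(status = "skipped")
  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  manifest$n_genes_universe <- if (!is.null(res$calls))
    length(res$calls$genes) else NA_integer_
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
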