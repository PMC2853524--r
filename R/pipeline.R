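# Workflow orchestration: the two headline analyses behind one call each,
# with reproducible run metadata (config hash, seed, package version) stamped
# into every output bundle.

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_metadata <- function(output_dir, config, extra = list()) {
  meta <- c(list(package = "switchFBA",
                 version = as.character(utils::packageVersion("switchFBA")),
                 config = config, config_hash = config_hash(config)),
            extra)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(output_dir, "run_metadata.json"))
  meta
}

#' Chemostat validation workflow
#'
#' Loads (or takes) a model and a condition table, runs [chemostat_panel()],
#' and writes the predicted-vs-observed table together with a scatter
#' summary (observed dilution rate vs predicted growth rate) and run
#' metadata.
#'
#' @param model a `metabolic_model` or an SBML path.
#' @param conditions a condition data.frame or a TSV path
#'   (see [read_chemostat_table()]).
#' @param exchange_map as in [chemostat_panel()].
#' @param output_dir created if missing.
#' @param ... passed to [chemostat_panel()].
#' @return the panel data.frame, invisibly; files written:
#'   `chemostat_panel.tsv`, `chemostat_summary.json`, `run_metadata.json`.
#' @export
run_chemostat_validation <- function(model, conditions, exchange_map,
                                     output_dir, ...) {
  if (is.character(model)) model <- read_sbml(model)
  if (is.character(conditions)) conditions <- read_chemostat_table(conditions)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(conditions) == 0L)
    warning("empty condition table; writing an empty report")
  panel <- chemostat_panel(model, conditions, exchange_map, ...)
  write_tsv(as.data.frame(panel), file.path(output_dir, "chemostat_panel.tsv"))
  obs <- panel$observed_dilution_rate
  summary <- list(n_conditions = nrow(panel))
  if (!is.null(obs) && nrow(panel) > 0 && !all(is.na(obs))) {
    summary$rmse <- sqrt(mean((obs - panel$predicted_mu)^2, na.rm = TRUE))
    summary$max_abs_error <- max(abs(obs - panel$predicted_mu), na.rm = TRUE)
    if (nrow(panel) > 2 && stats::sd(obs, na.rm = TRUE) > 0)
      summary$pearson_r <- stats::cor(obs, panel$predicted_mu,
                                      use = "complete.obs")
  }
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(output_dir, "chemostat_summary.json"))
  run_metadata(output_dir, list(workflow = "chemostat_validation",
                                n_conditions = nrow(panel)))
  invisible(panel)
}

#' Metabolic-switch analysis workflow
#'
#' The full integration pipeline: time-resolved FBA under the schedule,
#' gene-reaction matching, flux-expression correlation and classification,
#' hierarchical clustering, genome-order track, and the zero-flux and
#' essentiality screens. All outputs are TSV/JSON under `output_dir`; any
#' stage failure aborts with the stage named and removes partial outputs.
#'
#' @param model a `metabolic_model` or SBML path.
#' @param schedule a `constraint_schedule`.
#' @param expr an `expression_matrix` or TSV path.
#' @param output_dir created if missing.
#' @param r_low,r_high correlation class thresholds.
#' @param k_clusters number of expression clusters.
#' @param objective_mode `"weighted"` or `"forced"` (see [run_dynamic_fba()]).
#' @param weight_scale antibiotic objective scaling.
#' @param gene_order chromosomal gene order; defaults to sorted gene ids.
#' @param low_cutoff low-expression flag threshold (log2).
#' @param seed stored in the metadata (the pipeline itself is
#'   deterministic).
#' @return invisibly, a list with the flux series, report, assignment,
#'   screens and metadata.
#' @export
run_switch_analysis <- function(model, schedule, expr, output_dir,
                                r_low = -0.5, r_high = 0.5, k_clusters = 12,
                                objective_mode = "weighted", weight_scale = 1,
                                gene_order = NULL, low_cutoff = 5.0,
                                seed = NULL) {
  stopifnot(r_low < r_high, k_clusters >= 1)
  if (is.character(model)) model <- read_sbml(model)
  if (is.character(expr)) expr <- read_expression(expr)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- write_tsv(df, file.path(output_dir, name))
    written <<- c(written, p)
    p
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop("switch analysis failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  fluxTS <- stage("dynamic_fba", run_dynamic_fba(model, schedule,
                                                 objective_mode = objective_mode,
                                                 weight_scale = weight_scale))
  emit(data.frame(reaction = rownames(fluxTS$flux_matrix),
                  fluxTS$flux_matrix, check.names = FALSE), "flux_matrix.tsv")
  emit(data.frame(time_h = fluxTS$times, mu = unname(fluxTS$growth_curve),
                  status = fluxTS$status), "growth_curve.tsv")

  matching <- stage("gene_matching", match_genes(model, fluxTS))
  report <- stage("correlation", {
    r <- correlate(fluxTS, expr, matching)
    classify(r, low = r_low, high = r_high)
  })
  emit(report$profiles, "gene_correlations.tsv")

  assignment <- stage("clustering", {
    genes <- report$profiles$gene
    sub <- expression_matrix(expr$values[genes, , drop = FALSE], expr$times)
    hierarchical_clusters(sub, k = min(k_clusters, length(genes)))
  })
  emit(data.frame(gene = names(assignment$cluster),
                  cluster = unname(assignment$cluster)), "clusters.tsv")
  emit(data.frame(cluster = rownames(assignment$mean_profiles),
                  size = assignment$sizes, assignment$mean_profiles,
                  check.names = FALSE), "cluster_mean_profiles.tsv")

  if (is.null(gene_order)) gene_order <- sort(names(assignment$cluster))
  track <- stage("genome_track", genome_track(assignment, report, gene_order))
  emit(track, "genome_track.tsv")

  zf <- stage("zero_flux_screen", zero_flux_genes(matching, fluxTS))
  ess <- stage("essentiality_screen",
               essential_expression_summary(fluxTS, expr, matching,
                                            low_cutoff = low_cutoff))
  emit(data.frame(gene = zf), "zero_flux_genes.tsv")
  emit(data.frame(gene = ess$essential_genes), "essential_genes.tsv")

  summary <- list(
    class_counts = as.list(report$class_counts),
    class_fractions = as.list(attr(report$class_counts, "fractions")),
    n_genes_matched = length(matching),
    n_excluded = sum(report$profiles$excluded),
    n_zero_flux = length(zf),
    n_essential = length(ess$essential_genes),
    median_essential = ess$median_essential,
    median_non_essential = ess$median_non_essential,
    median_controls = ess$median_controls,
    n_low_expressed_essential = length(ess$low_expressed_essential),
    resolution_method = fluxTS$resolution_method,
    objective_mode = objective_mode)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(output_dir, "switch_summary.json"))
  meta <- run_metadata(output_dir,
                       list(workflow = "switch_analysis", r_low = r_low,
                            r_high = r_high, k_clusters = k_clusters,
                            objective_mode = objective_mode,
                            weight_scale = weight_scale,
                            low_cutoff = low_cutoff, seed = seed))
  invisible(list(fluxTS = fluxTS, matching = matching, report = report,
                 assignment = assignment, track = track,
                 zero_flux = zf, essential = ess, summary = summary,
                 metadata = meta))
}
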