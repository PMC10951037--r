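# End-to-end orchestration: select specimens -> drop never-expressed ->
# z-scores -> two-phase trajectory -> centile benchmark -> gene filters
# -> genome-wide correlation -> thresholded sets -> enrichment. Every
# stage writes a TSV under the output directory and contributes counts
# to a run manifest, so the run is auditable stage by stage.

#' Assemble a pipeline configuration
#'
#' All defaults are the analysis constants of the pipeline: inclusion
#' needs at least 4 non-cerebellar regions, elevation means z > 1.96,
#' the co-expression thresholds are r > 0.6 / r < -0.6, the missingness
#' cap is 5 of the included specimens, and the quartile filter is on.
#'
#' @param matrix_path,rows_meta_path,columns_meta_path BrainSpan-dialect
#'   input triplet (see [read_brainspan()]).
#' @param gmt_path optional GMT annotation file; `NULL` disables the
#'   enrichment stage.
#' @param out_dir output directory.
#' @param target_gene target gene symbol or id (default `"ATM"`).
#' @param min_other_regions,elevation_threshold,max_missing_z,upper_r,lower_r
#'   analysis constants (see module functions).
#' @param quartile_filter logical; apply the lowest-quartile expression
#'   filter.
#' @param first_year_in_phase2 phase-membership convention, see
#'   [default_phases()].
#' @param log_transform z-score `log2(x+1)` values instead of raw RPKM.
#' @param cerebellar_labels structure acronyms counted as cerebellar.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix_path, rows_meta_path, columns_meta_path,
                       gmt_path = NULL, out_dir = "brainrelz_out",
                       target_gene = "ATM", min_other_regions = 4L,
                       elevation_threshold = 1.96, max_missing_z = 5L,
                       upper_r = 0.6, lower_r = -0.6,
                       quartile_filter = TRUE,
                       first_year_in_phase2 = TRUE,
                       log_transform = FALSE,
                       cerebellar_labels = cerebellar_labels_default) {
  stopifnot(min_other_regions >= 0, elevation_threshold > 0,
            upper_r > lower_r, max_missing_z >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error.
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop(path, ": unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage, writes per-stage TSVs plus a `manifest.yaml`
#' under `cfg$out_dir`, and returns all stage results.
#'
#' @param cfg a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with elements `dataset`, `selection`,
#'   `never_expressed`, `zm`, `trajectory`, `centiles`, `filter`,
#'   `correlations`, `sets`, `enrichment` (NULL when no GMT) and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- stage("read", read_brainspan(cfg$matrix_path, cfg$rows_meta_path,
                                     cfg$columns_meta_path,
                                     cerebellar_labels = cfg$cerebellar_labels))
  sel <- stage("select_specimens",
               select_specimens(ds, min_other_regions = cfg$min_other_regions))
  data.table::fwrite(sel$excluded, file.path(cfg$out_dir, "excluded_specimens.tsv"),
                     sep = "\t")
  ne <- stage("drop_never_expressed", drop_never_expressed(sel$included))
  target <- stage("resolve_target", resolve_gene(ne$kept, cfg$target_gene))
  zm <- stage("relative_z", relative_z(ne$kept,
                                       log_transform = cfg$log_transform))
  write_relz(zm, file.path(cfg$out_dir, "relative_z.tsv"))

  phases <- default_phases(first_year_in_phase2 = cfg$first_year_in_phase2)
  traj <- stage("trajectory",
                two_phase_report(zm, target, phases,
                                 elevation_threshold = cfg$elevation_threshold))
  write_trajectory(traj, file.path(cfg$out_dir, "trajectory_fits.tsv"),
                   file.path(cfg$out_dir, "trajectory_specimens.tsv"))

  cent <- stage("centile_benchmark", centile_benchmark(zm, target))
  data.table::fwrite(as.data.frame(cent),
                     file.path(cfg$out_dir, "centile_report.tsv"), sep = "\t")

  filt <- stage("filter_genes", {
    f <- filter_genes(ne$kept, zm, max_missing_z = cfg$max_missing_z)
    if (!cfg$quartile_filter) {
      keep <- rownames(zm$z)[rowSums(is.na(zm$z)) <= cfg$max_missing_z]
      f$retained_genes <- keep
      f$report$n_low_expression_dropped <- 0L
      f$report$quartile_threshold <- NA_real_
      f$report$n_retained <- length(keep)
    }
    f
  })
  data.table::fwrite(filt$report, file.path(cfg$out_dir, "gene_filter_report.tsv"),
                     sep = "\t")

  ct <- stage("correlate_all",
              correlate_all(zm, target, setdiff(filt$retained_genes, target)))
  data.table::fwrite(ct, file.path(cfg$out_dir, "correlations.tsv"),
                     sep = "\t", na = "")
  sets <- stage("build_sets", build_sets(ct, upper = cfg$upper_r,
                                         lower = cfg$lower_r))
  write_gene_sets(sets, cfg$out_dir, prefix = cfg$target_gene)

  enr <- NULL
  if (!is.null(cfg$gmt_path)) {
    enr <- stage("enrich", {
      ann <- read_gmt(cfg$gmt_path)
      universe <- intersect(filt$retained_genes, ann$universe)
      list(positive = enrich(intersect(sets$positive, universe), ann, universe),
           negative = enrich(intersect(sets$negative, universe), ann, universe))
    })
    write_enrichment(enr$positive,
                     file.path(cfg$out_dir, "enrichment_positive.tsv"))
    write_enrichment(enr$negative,
                     file.path(cfg$out_dir, "enrichment_negative.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("brainrelz")),
    target_gene = target,
    n_donors_input = nrow(ds$specimens),
    n_specimens_included = nrow(sel$included$specimens),
    n_specimens_excluded = nrow(sel$excluded),
    n_genes_input = nrow(ds$values) - 1L,
    n_never_expressed = length(ne$dropped_genes),
    n_genes_analysed = nrow(ne$kept$values) - 1L,
    n_degenerate_z_cells = zm$n_degenerate,
    quartile_threshold = filt$report$quartile_threshold,
    n_after_quartile_filter = filt$report$n_input -
      filt$report$n_low_expression_dropped,
    n_in_correlation_analysis = filt$report$n_retained,
    trajectory = lapply(traj$fits, function(f) {
      list(phase = f$phase$name, n = f$n, r = f$r, p = f$p)
    }),
    n_positive_set = length(sets$positive),
    n_negative_set = length(sets$negative),
    config = lapply(cfg[setdiff(names(cfg), "cerebellar_labels")],
                    function(x) if (is.null(x)) NA else x)
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(dataset = ds, selection = sel, never_expressed = ne,
                 zm = zm, trajectory = traj, centiles = cent,
                 filter = filt, correlations = ct, sets = sets,
                 enrichment = enr, manifest = manifest))
}
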