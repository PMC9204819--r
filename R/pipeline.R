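#' Default pipeline configuration
#'
#' A serializable description of a complete benchmark run: mixing design,
#' simulation parameters (interference given as beta shape parameters so the
#' config round-trips through YAML), notch boundaries, filtering selection,
#' contrasts, FDR threshold, aggregation level, output directory and the
#' global seed.
#'
#' @param outdir Output directory for the run.
#' @param seed Global integer seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(outdir = tempfile("notchbench_run_"),
                           seed = 1234L) {
  structure(list(
    design = list(yeast_by_group = c("1x" = 5, "2x" = 10, "6x" = 30),
                  total_mass = 100),
    params = list(n_yeast_proteins = 180, n_human_proteins = 620,
                  psm_mean = 4, psm_dispersion = 1,
                  mean_log2_abundance = 11, base_abundance_sd = 2.5,
                  psm_scale_sd = 1, reporter_noise_sd = 0.15,
                  interference_shape1 = 1.5, interference_shape2 = 13.5,
                  missing_rate = 0.3, detection_floor = 3,
                  notch_enabled = TRUE, notch_slope = 1, sn_noise = 16,
                  sn_spread_sd = 1),
    notch = c(lower = 4.25, upper = 5.75),
    grid = TRUE,
    schema = list(min_delta_cn = 0.5, max_coisolation = 10,
                  min_avg_sn = 10, remove_notch = FALSE),
    contrasts = list(c("2x", "1x"), c("6x", "1x")),
    fdr_threshold = 0.01,
    level = "protein",
    outdir = outdir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Validate a run configuration against all stage preconditions
#'
#' @param config A `run_config` list (see [default_config()]).
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  req <- c("design", "params", "notch", "grid", "schema", "contrasts",
           "fdr_threshold", "level", "outdir", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing)) stop("config missing field(s): ",
                            paste(missing, collapse = ", "))
  with(config$design, {
    if (any(yeast_by_group <= 0) || any(yeast_by_group >= total_mass))
      stop("config design: yeast masses must be in (0, total_mass)")
  })
  if (!config$grid && isTRUE(config$schema$remove_notch) &&
      (is.null(config$notch) || anyNA(config$notch))) {
    stop("config: notch boundaries required when remove_notch is set")
  }
  if (config$notch[["lower"]] >= config$notch[["upper"]]) {
    stop("config: notch lower boundary must be below upper")
  }
  if (config$fdr_threshold <= 0 || config$fdr_threshold >= 1) {
    stop("config: fdr_threshold must lie in (0, 1)")
  }
  if (!config$level %in% c("protein", "peptide")) {
    stop("config: level must be 'protein' or 'peptide'")
  }
  # construct the parameter objects so their own validation runs
  config_sim_params(config)
  invisible(config)
}

# Internal: materialize sim_params from the serializable config.
config_sim_params <- function(config) {
  p <- config$params
  s1 <- p$interference_shape1
  s2 <- p$interference_shape2
  interference <- if (s1 <= 0 || s2 <= 0) {
    function(n) rep(0, n)
  } else {
    function(n) stats::rbeta(n, s1, s2)
  }
  sim_params(
    n_yeast_proteins = p$n_yeast_proteins,
    n_human_proteins = p$n_human_proteins,
    psm_per_protein = c(mean = p$psm_mean, dispersion = p$psm_dispersion),
    mean_log2_abundance = p$mean_log2_abundance,
    base_abundance_sd = p$base_abundance_sd,
    psm_scale_sd = p$psm_scale_sd,
    reporter_noise_sd = p$reporter_noise_sd,
    interference_dist = interference,
    missing_rate = p$missing_rate,
    detection_floor = p$detection_floor,
    notch = if (isTRUE(p$notch_enabled)) {
      notch_region(config$notch[["lower"]], config$notch[["upper"]])
    } else NULL,
    notch_slope = p$notch_slope,
    sn_noise = p$sn_noise,
    sn_spread_sd = p$sn_spread_sd,
    seed = config$seed
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the parsed
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # YAML keeps names for mappings, not atomic vectors
  cfg$design$yeast_by_group <- as.list(cfg$design$yeast_by_group)
  cfg$notch <- as.list(cfg$notch)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$design$yeast_by_group <- unlist(cfg$design$yeast_by_group)
  cfg$notch <- unlist(cfg$notch)
  cfg$contrasts <- lapply(cfg$contrasts, unlist)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the complete benchmark pipeline from one configuration
#'
#' Simulates the spike-in experiment, normalizes, runs either the 36-schema
#' grid or one configured schema (filter, aggregate, test, score), and the
#' paired with/without notch-filtering comparison, writing every table as
#' TSV under `config$outdir` and a YAML manifest listing the files, stage
#' record counts, package version and seed.
#'
#' @param config A `run_config` (see [default_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  files <- character()
  counts <- list()

  design <- build_mix_design(config$design$yeast_by_group,
                             config$design$total_mass)
  params <- config_sim_params(config)
  sim <- simulate_experiment(design, params)
  notch <- notch_region(config$notch[["lower"]], config$notch[["upper"]])

  write_psm_table(sim$table, out("psm_table.tsv"))
  readr::write_tsv(sim$truth$expected, out("ground_truth.tsv"),
                   progress = FALSE)
  files <- c(files, out("psm_table.tsv"), out("ground_truth.tsv"))
  counts$simulated_psms <- nrow(sim$table$psms)

  norm <- center_median_normalize(sim$table)
  stats_tbl <- notch_stats(norm, notch)
  readr::write_tsv(stats_tbl, out("notch_stats.tsv"), progress = FALSE)
  files <- c(files, out("notch_stats.tsv"))

  if (isTRUE(config$grid)) {
    grid_tbl <- run_grid(norm, notch, sim$truth, level = config$level,
                         contrasts = config$contrasts,
                         fdr_threshold = config$fdr_threshold)
    readr::write_tsv(grid_tbl, out("grid_evaluation.tsv"), progress = FALSE)
    files <- c(files, out("grid_evaluation.tsv"))
    counts$grid_rows <- nrow(grid_tbl)
    counts$schemas <- length(unique(grid_tbl$schema))
  }

  # paired with/without notch-filtering comparison under the configured
  # threshold triple
  sc <- config$schema
  base_schema <- filter_schema(sc$min_delta_cn, sc$max_coisolation,
                               sc$min_avg_sn, remove_notch = FALSE)
  rm_schema <- filter_schema(sc$min_delta_cn, sc$max_coisolation,
                             sc$min_avg_sn, remove_notch = TRUE)
  f_keep <- apply_filters(norm, base_schema, notch)
  f_rm <- apply_filters(norm, rm_schema, notch)
  fm_keep <- aggregate_psms(f_keep$table, level = config$level)
  fm_rm <- aggregate_psms(f_rm$table, level = config$level)
  res_keep <- fit_moderated_test(fm_keep, contrasts = config$contrasts)
  res_rm <- fit_moderated_test(fm_rm, contrasts = config$contrasts)
  exposure <- notch_exposure(f_keep$table, fm_keep, notch)
  affected <- exposure$feature_id[exposure$max_fraction > 0]
  cmp <- compare_notch_filtering(res_rm, res_keep, sim$truth, affected)
  readr::write_tsv(cmp$delta, out("notch_filtering_delta.tsv"),
                   progress = FALSE)
  files <- c(files, out("notch_filtering_delta.tsv"))
  counts$psms_after_filter <- f_keep$report$output_count
  counts$features <- nrow(fm_keep$features)
  counts$affected_features <- length(affected)

  manifest <- list(package = "notchbench",
                   version = as.character(utils::packageVersion("notchbench")),
                   seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   files = files, counts = counts)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  stopifnot(all(file.exists(files)))
  invisible(manifest)
}
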