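#' Read a pipeline configuration from JSON
#'
#' The configuration is a nested list with optional blocks `annotation`,
#' `sites`, `enrichment`, `profiles`, `filter`, `geometry`, `hotspot`,
#' `dwell`, `thresholds`, plus a global `seed`. Each input block either
#' names a `path` to read or a `simulate` block of generator arguments.
#'
#' @param path JSON file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_input("[stage %s] %s", stage, conditionMessage(e))
  })
}

log_line <- function(log_path, stage, message, ...) {
  if (is.null(log_path)) return(invisible())
  entry <- c(list(level = "INFO", stage = stage, message = message), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible()
}

config_block <- function(config, name) config[[name]] %||% list()

build_annotation <- function(config) {
  blk <- config_block(config, "annotation")
  if (!is.null(blk$path)) return(read_domain_annotation(blk$path))
  do.call(sim_annotation, config_block(blk, "simulate"))
}

build_design <- function(blk) {
  sample_design(blk$design$sample, blk$design$genotype)
}

report_header <- function(config) {
  list(seed = config$seed %||% NA, config_md5 = md5_of_object(config))
}

#' Run the biotinylation-site stage of the pipeline
#'
#' Reads or simulates a site table, applies the knock-in-specificity
#' filter, annotates sites with domain segments, detects hotspots, and
#' derives the secondary/primary intensity ratio, the ligase radius
#' estimate, and the dwell fraction and time. Writes the retained sites as
#' TSV and a JSON hotspot report into `out_dir`.
#'
#' @param config configuration list (see [read_pipeline_config()]); the
#'   `sites` block must carry either `path` + `design` or a `simulate`
#'   block, and `insertion_residue` must be available from the simulate
#'   block or `config$insertion_residue`.
#' @param out_dir output directory, created if needed.
#' @return list with `table` (filtered, annotated [site_table()]),
#'   `hotspots`, and the `report` list, invisibly written as
#'   `hotspot_report.json`.
#' @export
run_sites <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  annotation <- with_stage("annotation", build_annotation(config))
  blk <- config_block(config, "sites")
  geom <- do.call(geometry_model, config_block(config, "geometry"))

  table <- with_stage("sites_input", {
    if (!is.null(blk$path)) {
      read_site_table(blk$path, build_design(blk))
    } else {
      args <- config_block(blk, "simulate")
      if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
      simulate_site_table(do.call(sim_config, args), annotation, geom)
    }
  })
  log_line(log_path, "sites_input", "site table loaded", n_sites = nrow(table))

  fp <- do.call(filter_params, config_block(config, "filter"))
  filtered <- with_stage("filter_specific_sites", filter_specific_sites(table, fp))
  log_line(log_path, "filter_specific_sites", "knock-in-specific sites kept",
           n_input = nrow(table), n_kept = nrow(filtered))

  annotated <- with_stage("annotate_sites", annotate_sites(filtered, annotation))
  hs_blk <- config_block(config, "hotspot")
  hotspots <- with_stage("detect_hotspots", {
    detect_hotspots(annotated, annotation, geom,
                    merge_gap_nm = hs_blk$merge_gap_nm %||% 30)
  })
  log_line(log_path, "detect_hotspots", "hotspots detected", n = nrow(hotspots))

  dp <- do.call(dwell_params, config_block(config, "dwell"))
  insertion <- config$insertion_residue %||% blk$simulate$insertion_residue
  primary <- hotspot_by_rank(hotspots, "primary")
  secondary <- hotspot_by_rank(hotspots, "secondary")

  ratio <- if (!is.null(primary) && !is.null(secondary)) {
    hotspot_ratio(secondary, primary)
  } else NA_real_
  frac <- if (is.finite(ratio)) dwell_fraction(ratio, dp) else NA_real_
  radius <- if (!is.null(primary) && !is.null(insertion)) {
    with_stage("estimate_radius",
               estimate_radius(annotation, insertion, primary, geom))
  } else c(min_nm = NA_real_, max_nm = NA_real_)

  hs_report <- as.data.frame(hotspots)[setdiff(names(hotspots), "members")]
  report <- c(report_header(config), list(
    n_sites_input = nrow(table),
    n_sites_kept = nrow(filtered),
    hotspots = hs_report,
    secondary_primary_ratio = ratio,
    radius_nm = as.list(radius),
    dwell_fraction = frac,
    dwell_time_s = if (is.finite(frac)) dwell_time(frac, dp) else NA_real_))

  write_site_table(annotated, file.path(out_dir, "retained_sites.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "hotspot_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(list(table = annotated, hotspots = hotspots, report = report))
}

#' Run the protein-enrichment stage of the pipeline
#'
#' Reads or simulates a protein-group table and applies valid-value
#' filtering, log2 transform, down-shifted imputation, the two-sample
#' Student's t-test, permutation FDR and the associated-protein call.
#' Writes a volcano-style TSV (`log2fc`, `-log10 p`, `q`, `significant`)
#' and a JSON report.
#'
#' @param config configuration list; the `enrichment` block carries either
#'   `path` + `design` or a `simulate` block, plus optional `min_valid`,
#'   `imputation`, `fdr` and `min_peptides` settings.
#' @param out_dir output directory.
#' @return list with `results` (TestResult data.frame) and `called`
#'   (character vector of enriched protein ids).
#' @export
run_enrichment <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  blk <- config_block(config, "enrichment")
  truth <- NULL
  table <- with_stage("enrichment_input", {
    if (!is.null(blk$path)) {
      read_proteingroups(blk$path, build_design(blk))
    } else {
      args <- config_block(blk, "simulate")
      if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
      sim <- simulate_proteingroups(do.call(sim_config, args))
      truth <<- sim$truth
      sim$table
    }
  })
  log_line(log_path, "enrichment_input", "protein groups loaded", n = nrow(table))

  results <- with_stage("enrich_proteins", {
    enrich_proteins(table,
                    min_valid = blk$min_valid %||% 3L,
                    imputation = do.call(imputation_params,
                                         config_block(blk, "imputation")),
                    fdr_params = do.call(permutation_fdr_params,
                                         config_block(blk, "fdr")),
                    min_peptides = blk$min_peptides %||% 3L,
                    seed = config$seed %||% NULL)
  })
  called <- attr(results, "called") %||% character(0)
  log_line(log_path, "enrich_proteins", "enrichment computed",
           n_tested = nrow(results), n_called = length(called))

  volcano <- data.frame(protein_id = results$protein_id,
                        log2fc = results$log2fc,
                        minus_log10_p = -log10(results$p),
                        q = results$q, significant = results$significant,
                        stringsAsFactors = FALSE)
  utils::write.table(volcano, file.path(out_dir, "volcano.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- c(report_header(config),
              list(n_input = nrow(table), n_tested = nrow(results),
                   called = called,
                   truth = truth))
  jsonlite::write_json(report, file.path(out_dir, "enrichment_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(list(results = results, called = called, truth = truth))
}

#' Run the profile-quantification stage of the pipeline
#'
#' Reads or simulates sarcomere line profiles and measures, per profile,
#' the sarcomere length, Z-disc width and edges, myosin filament edges at
#' the 75% threshold, biotin/myosin overlap intervals at the >25%
#' threshold, and the secondary-hotspot displacement from the Z-disc edge.
#' Writes a per-profile measurement TSV, mean +/- SEM averaged traces as
#' CSV, and a JSON summary.
#'
#' @param config configuration list; the `profiles` block carries either
#'   `paths` (CSV files) or a `simulate` block of [simulate_profiles()]
#'   arguments, plus optional `thresholds`.
#' @param out_dir output directory.
#' @return list with `measurements` (data.frame), `traces` (averaged
#'   trace), and the `report` list.
#' @export
run_profiles <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  blk <- config_block(config, "profiles")
  profiles <- with_stage("profiles_input", {
    if (!is.null(blk$paths)) {
      lapply(blk$paths, read_profile)
    } else {
      args <- config_block(blk, "simulate")
      if (!is.null(config$seed) && is.null(args$seed)) args$seed <- config$seed
      do.call(simulate_profiles, args)
    }
  })
  log_line(log_path, "profiles_input", "profiles loaded", n = length(profiles))
  thresholds <- do.call(profile_thresholds, config_block(blk, "thresholds"))

  measurements <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    with_stage(sprintf("profile_%d", i),
               measure_profile(profiles[[i]], thresholds, replicate = i))
  }))
  traces <- with_stage("average_profiles", average_profiles(profiles))

  utils::write.table(measurements, file.path(out_dir, "profile_measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(traces),
                   file.path(out_dir, "averaged_traces.csv"), row.names = FALSE)
  summarize <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(list(mean = NA, sem = NA, n = 0L))
    list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }
  report <- c(report_header(config), list(
    n_profiles = length(profiles),
    sarcomere_length_um = summarize(measurements$sarcomere_length_um),
    zdisc_width_nm = summarize(measurements$zdisc_width_nm),
    hotspot_displacement_nm = summarize(measurements$hotspot_displacement_nm),
    overlap_total_nm = summarize(measurements$overlap_total_nm)))
  jsonlite::write_json(report, file.path(out_dir, "profile_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(list(measurements = measurements, traces = traces, report = report))
}

#' Measure one sarcomere profile
#'
#' Applies the full band/overlap/displacement measurement battery to a
#' single profile: actinin peak spacing and central-band FWHM, Z-disc
#' half-max edges, biotin/myosin overlap and the secondary-hotspot
#' displacement, all within an analysis window of one sarcomere centered
#' on the central Z-disc.
#'
#' @param profile an [intensity_profile()] with `actinin`, `biotin` and
#'   `myosin` channels.
#' @param thresholds a [profile_thresholds()].
#' @param replicate replicate id recorded in the output row.
#' @return one-row data.frame of measurements.
#' @export
measure_profile <- function(profile, thresholds = profile_thresholds(),
                            replicate = NA_integer_) {
  for (ch in c("actinin", "biotin", "myosin")) get_channel(profile, ch)
  sarc <- measure_sarcomere(profile, "actinin", thresholds)
  sl_nm <- sarc$sarcomere_length_um * 1000
  center <- mean(range(profile$position_nm))
  z_center <- sarc$peak_positions_nm[which.min(abs(sarc$peak_positions_nm - center))]
  box <- window_profile(profile, z_center - sl_nm / 2, z_center + sl_nm / 2)
  z_edges <- band_halfmax_edges(box, "actinin", z_center)
  ov <- overlap_intervals(box, "biotin", "myosin", thresholds)
  myo_edges <- find_edges(box, "myosin", thresholds)
  disp <- hotspot_displacement(box, "biotin", z_edges, thresholds)
  data.frame(replicate = replicate,
             sarcomere_length_um = sarc$sarcomere_length_um,
             zdisc_width_nm = sarc$zdisc_width_nm,
             zdisc_edge_left_nm = z_edges[1L],
             zdisc_edge_right_nm = z_edges[2L],
             n_myosin_edges = nrow(myo_edges),
             n_overlap_intervals = nrow(ov),
             overlap_total_nm = sum(ov$end - ov$start),
             hotspot_displacement_nm = disp)
}
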