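#' Default pipeline configuration
#'
#' All protocol defaults in one place: truth sampling step 5,000 bp and 1 cM
#' minimum, 50% coverage threshold, length bins from 2 to 7 cM plus an
#' open-ended bin, array target of 17,197 markers with window 5, 0.1%
#' genotyping-error rate, 2 cM coverage-profile cutoff, relatedness degrees
#' up to 4. A near-empty user config therefore reproduces the full protocol
#' shape.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    chrom = "1",
    outdir = "ibdbench_out",
    plots = FALSE,
    paths = list(map = NULL, track = NULL, panel = NULL, truth = NULL,
                 calls = NULL),
    map_dialect = "plink",
    calls_format = "truth",   # "truth", "hapibd" or "generic"
    calls_column_map = NULL,
    truth = list(sample_step_bp = 5000, min_length_cm = 1.0),
    downsample = list(target_sites = 17197, window = 5),
    errors = list(rate = 0.001),
    metrics = list(coverage_threshold = 0.5,
                   bin_edges_cm = c(2, 3, 4, 5, 6, 7),
                   pair_mode = "haplotype"),
    coverage = list(min_length_cm = 2.0),
    relatedness = list(genome_length_cm = NULL, max_degree = 4),
    simulate = list(n_haplotypes = 200, region_bp = 1e7,
                    mean_segment_bp = 2e6, cm_per_mb = 1, n_sites = 5000,
                    perturb = list(boundary_jitter_cm = 0.1,
                                   fragmentation_prob = 0.1, gap_cm = 0.2,
                                   false_positive_rate = 0.05,
                                   drop_rate = 0.05))
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (if given) and merges it recursively over
#' [default_config()]; `overrides` merge last.
#'
#' @param path Optional YAML config file.
#' @param overrides Optional named list of overrides.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_rec <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(extra[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], extra[[nm]])
      } else base[[nm]] <- extra[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- merge_rec(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_rec(cfg, overrides)
  cfg
}

.cfg_metric <- function(config) {
  m <- config$metrics
  metric_config(coverage_threshold = m$coverage_threshold,
                bin_edges_cm = m$bin_edges_cm,
                pair_mode = m$pair_mode)
}

.stage_path <- function(config, name, default_file) {
  p <- config$paths[[name]]
  if (!is.null(p)) p else file.path(config$outdir, default_file)
}

.need_file <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("missing input for %s: %s", what, path))
  }
  path
}

.write_manifest <- function(config, stage, inputs, outputs) {
  man <- list(stage = stage, seed = config$seed,
              config_hash = rlang::hash(config),
              package_version = as.character(utils::packageVersion("ibdbench")),
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(man, file.path(config$outdir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.read_calls_cfg <- function(config, map) {
  path <- .need_file(.stage_path(config, "calls", "calls.tsv"), "eval")
  fmt <- config$calls_format
  if (fmt == "truth") {
    add_genetic_coords(read_truth_ibd(path), map)
  } else if (fmt == "hapibd") {
    read_ibd_calls(path, ibd_dialect("hapibd"), map)
  } else {
    read_ibd_calls(path, ibd_dialect("generic",
                                     column_map = config$calls_column_map),
                   map)
  }
}

#' Run the benchmarking pipeline
#'
#' Orchestrates the stages on disk. Subcommands:
#' * `simulate` — generate a seeded synthetic map, local-tree track and
#'   haplotype panel under `config$simulate`;
#' * `truth` — extract ground-truth IBD from the track;
#' * `downsample` — array-density panel from the (filtered) panel;
#' * `errors` — genotyping-error-perturbed panel;
#' * `eval` — score the call file against the truth file (report TSV + JSON);
#' * `coverage` — per-site coverage profiles of truth and calls;
#' * `relatedness` — total-IBD degree tables for truth and calls;
#' * `all` — everything above; when no call file is supplied, reported calls
#'   are produced by the pseudo-caller perturbation of the truth set.
#'
#' Every stage writes a manifest (stage, seed, config hash, inputs, outputs);
#' reruns with the same config and seed are byte-identical.
#'
#' @param config Configuration list from [load_config()].
#' @param subcommand One of the stage names above.
#' @return Invisibly, a named list of output paths (for `eval`, also the
#'   `metric_report`).
#' @export
run_pipeline <- function(config = default_config(),
                         subcommand = c("all", "simulate", "truth",
                                        "downsample", "errors", "eval",
                                        "coverage", "relatedness")) {
  if (length(subcommand) != 1 || !subcommand %in%
      c("all", "simulate", "truth", "downsample", "errors", "eval",
        "coverage", "relatedness")) {
    stop("unknown subcommand: ", paste(subcommand, collapse = ","))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  get_map <- function() {
    p <- .need_file(.stage_path(config, "map", "map.map"), "genetic map")
    read_genetic_map(p, dialect = config$map_dialect)
  }

  if (subcommand %in% c("simulate", "all")) {
    sc <- config$simulate
    map <- uniform_map(sc$region_bp, cm_per_mb = sc$cm_per_mb,
                       chrom = config$chrom)
    map_path <- file.path(config$outdir, "map.map")
    writeLines(sprintf("%s\t%s\t%.6f\t%d", map$chrom,
                       paste0("m", seq_along(map$pos_bp)), map$pos_cm,
                       as.integer(map$pos_bp)), map_path)
    track <- gen_track(sc$n_haplotypes, sc$region_bp, sc$mean_segment_bp,
                       seed = config$seed, chrom = config$chrom)
    track_path <- file.path(config$outdir, "track.tsv")
    write_track(track, track_path)
    panel <- gen_panel(sc$n_haplotypes, sc$n_sites, seed = config$seed + 1L,
                       region_bp = sc$region_bp, chrom = config$chrom)
    panel_path <- file.path(config$outdir, "panel.vcf")
    write_vcf(panel, panel_path)
    message(sprintf("[simulate] %d runs, %d sites", nrow(track$runs),
                    nrow(panel$alleles)))
    out$map <- map_path; out$track <- track_path; out$panel <- panel_path
    config$paths$map <- map_path
    config$paths$track <- track_path
    config$paths$panel <- panel_path
    .write_manifest(config, "simulate", list(),
                    list(map = map_path, track = track_path,
                         panel = panel_path))
  }

  if (subcommand %in% c("truth", "all")) {
    map <- get_map()
    track_path <- .need_file(.stage_path(config, "track", "track.tsv"), "truth")
    track <- read_track(track_path)
    truth <- extract_truth_ibd(track, map,
                               sample_step_bp = config$truth$sample_step_bp,
                               min_length_cm = config$truth$min_length_cm)
    truth_path <- file.path(config$outdir, "truth.tsv")
    write_truth_ibd(truth, truth_path)
    message(sprintf("[truth] %d segments from %d runs", nrow(truth),
                    nrow(track$runs)))
    out$truth <- truth_path
    config$paths$truth <- truth_path
    .write_manifest(config, "truth",
                    list(track = track_path), list(truth = truth_path))
  }

  if (subcommand == "all" && is.null(config$paths$calls)) {
    # pseudo-caller: perturb the truth set into reported calls
    map <- get_map()
    truth <- add_genetic_coords(read_truth_ibd(config$paths$truth), map)
    pc <- config$simulate$perturb
    calls <- withr::with_seed(config$seed + 2L, do.call(perturb_segments, c(
      list(truth = truth, map = map), pc)))
    calls_path <- file.path(config$outdir, "calls.tsv")
    write_truth_ibd(calls, calls_path)
    message(sprintf("[pseudocall] %d calls from %d truth segments",
                    nrow(calls), nrow(truth)))
    out$calls <- calls_path
    config$paths$calls <- calls_path
    config$calls_format <- "truth"
    .write_manifest(config, "pseudocall",
                    list(truth = config$paths$truth),
                    list(calls = calls_path))
  }

  if (subcommand %in% c("downsample", "all")) {
    map <- get_map()
    panel_path <- .need_file(.stage_path(config, "panel", "panel.vcf"),
                             "downsample")
    panel <- filter_sites(read_vcf(panel_path))
    arr <- downsample_to_array(panel, map,
                               target_sites = config$downsample$target_sites,
                               window = config$downsample$window)
    arr_path <- file.path(config$outdir, "panel_array.vcf")
    write_vcf(arr, arr_path)
    message(sprintf("[downsample] %d -> %d sites", nrow(panel$alleles),
                    nrow(arr$alleles)))
    out$panel_array <- arr_path
    .write_manifest(config, "downsample", list(panel = panel_path),
                    list(panel_array = arr_path))
  }

  if (subcommand %in% c("errors", "all")) {
    panel_path <- .need_file(.stage_path(config, "panel", "panel.vcf"),
                             "errors")
    panel <- filter_sites(read_vcf(panel_path))
    inj <- inject_genotyping_errors(panel, rate = config$errors$rate,
                                    seed = config$seed + 3L)
    err_panel_path <- file.path(config$outdir, "panel_errors.vcf")
    err_path <- file.path(config$outdir, "errors.tsv")
    write_vcf(inj$panel, err_panel_path)
    utils::write.table(inj$errors, err_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("[errors] %d alleles flipped (rate %.4g)",
                    nrow(inj$errors), config$errors$rate))
    out$panel_errors <- err_panel_path; out$errors <- err_path
    .write_manifest(config, "errors", list(panel = panel_path),
                    list(panel_errors = err_panel_path, errors = err_path))
  }

  if (subcommand %in% c("eval", "all")) {
    map <- get_map()
    truth_path <- .need_file(.stage_path(config, "truth", "truth.tsv"), "eval")
    truth <- add_genetic_coords(read_truth_ibd(truth_path), map)
    calls <- .read_calls_cfg(config, map)
    report <- evaluate_binned(truth, calls, .cfg_metric(config))
    tsv <- file.path(config$outdir, "report.tsv")
    js <- file.path(config$outdir, "report.json")
    write_metric_report(report, tsv)
    write_metric_report(report, js)
    if (isTRUE(config$plots)) {
      p <- plot_metric_report(report)
      ggplot2::ggsave(file.path(config$outdir, "report.pdf"), p,
                      width = 9, height = 6)
    }
    message(sprintf("[eval] %d truth vs %d reported segments", nrow(truth),
                    nrow(calls)))
    out$report_tsv <- tsv; out$report_json <- js; out$report <- report
    .write_manifest(config, "eval",
                    list(truth = truth_path, calls = config$paths$calls),
                    list(report_tsv = tsv, report_json = js))
  }

  if (subcommand %in% c("coverage", "all")) {
    map <- get_map()
    truth_path <- .need_file(.stage_path(config, "truth", "truth.tsv"),
                             "coverage")
    truth <- add_genetic_coords(read_truth_ibd(truth_path), map)
    calls <- .read_calls_cfg(config, map)
    panel_path <- .stage_path(config, "panel", "panel.vcf")
    sites <- if (file.exists(panel_path)) read_vcf(panel_path)$pos_bp else
      seq(map$pos_bp[1], map$pos_bp[length(map$pos_bp)], length.out = 1000)
    for (nm in c("truth", "reported")) {
      segs <- if (nm == "truth") truth else calls
      cp <- coverage_profile(segs, sites,
                             min_length_cm = config$coverage$min_length_cm)
      p <- file.path(config$outdir, sprintf("coverage_%s.tsv", nm))
      utils::write.table(data.frame(pos_bp = cp$pos_bp, count = cp$count),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      out[[paste0("coverage_", nm)]] <- p
    }
    message("[coverage] profiles written")
    .write_manifest(config, "coverage",
                    list(truth = truth_path, calls = config$paths$calls),
                    list(truth = out$coverage_truth,
                         reported = out$coverage_reported))
  }

  if (subcommand %in% c("relatedness", "all")) {
    map <- get_map()
    truth_path <- .need_file(.stage_path(config, "truth", "truth.tsv"),
                             "relatedness")
    truth <- add_genetic_coords(read_truth_ibd(truth_path), map)
    calls <- .read_calls_cfg(config, map)
    gl <- config$relatedness$genome_length_cm
    if (is.null(gl)) gl <- map_total_cm(map)
    rcfg <- relatedness_config(gl, max_degree = config$relatedness$max_degree)
    rt <- relatedness_table(truth, calls, rcfg)
    p1 <- file.path(config$outdir, "relatedness.tsv")
    p2 <- file.path(config$outdir, "relatedness_counts.tsv")
    utils::write.table(rt$pairs, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(rt$counts, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("[relatedness] %d pairs", nrow(rt$pairs)))
    out$relatedness <- p1; out$relatedness_counts <- p2
    .write_manifest(config, "relatedness",
                    list(truth = truth_path, calls = config$paths$calls),
                    list(pairs = p1, counts = p2))
  }

  invisible(out)
}
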