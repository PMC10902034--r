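#' Run configuration
#'
#' Assembles and validates the configuration of an end-to-end synthetic
#' run: design parameters, rendering resolution, partitioning, invasion
#' extraction settings, number of structures and the master seed. Any
#' subset of fields can be overridden; unknown fields are rejected.
#'
#' @param ... overrides of the default fields.
#' @return validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    mode = "normal",           # "normal" or "dcis" invasion placement
    n_structures = 6,          # structures (independent seeds) per run
    stem_length = 1000, branch_length = 1000,
    branch_angle = 60, stroke_width = 100,
    pixel_size = 4, tip_fraction = 0.3,
    opening_radius_um = 30,    # um; the Fiji radius (30 px day-14 images,
                               # 20 px day-10) under a 1 um/px assumption
    min_component = 10,        # px
    seed = 1)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$mode %in% c("normal", "dcis"), cfg$n_structures >= 1,
            cfg$pixel_size > 0, cfg$tip_fraction > 0, cfg$tip_fraction < 1,
            cfg$opening_radius_um / cfg$pixel_size >= 1)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON (or YAML, when the yaml package is available) file.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package; use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(cfg)
}

#' Run the full synthetic analysis pipeline
#'
#' For each of `n_structures` seeded structures: generate a day-3/day-14
#' timecourse (invasion placement per `mode`), partition the day-14 mask,
#' and quantify growth expansion, invasion (extraction + outline-length
#' normalization), Ki67 ratios and viability. Group-level metrics are then
#' compared tips vs. trunk (paired across structures) and stem tip vs.
#' branch tips with the normality-gated procedure. All tables are written
#' as CSV together with a manifest (package version, config, seeds, file
#' checksums); reruns with the same config are bit-identical.
#'
#' @param config a [run_config()] (or list of overrides).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the tidy `metrics` table, the
#'   `comparisons` table, and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, ...) {
    msg <- jsonlite::toJSON(list(stage = stage, ...), auto_unbox = TRUE)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  design <- y_design(config$stem_length, config$branch_length,
                     config$branch_angle, config$stroke_width)
  metrics <- list()
  stage <- "setup"
  res <- tryCatch({
    for (i in seq_len(config$n_structures)) {
      seed_i <- config$seed + i - 1L
      stage <- sprintf("simulate[%d]", i)
      mk14 <- if (config$mode == "dcis") dcis_scene_params else scene_params
      tc <- generate_timecourse(
        day3_scene_params(design = design, pixel_size = config$pixel_size,
                          tip_fraction = config$tip_fraction, seed = seed_i),
        mk14(design = design, pixel_size = config$pixel_size,
             tip_fraction = config$tip_fraction, seed = seed_i))
      log_line(stage, seed = seed_i,
               n_nuclei = tc$day14$ground_truth$n_nuclei)

      stage <- sprintf("partition[%d]", i)
      part <- partition_regions(tc$day14$culture_mask, design,
                                config$tip_fraction)

      stage <- sprintf("growth[%d]", i)
      gr <- growth_expansion(tc$day3$culture_mask, tc$day14$culture_mask, part)

      stage <- sprintf("invasion[%d]", i)
      ext <- extract_invasion(tc$day14$culture_mask,
                              config$opening_radius_um / config$pixel_size,
                              config$min_component)
      ir <- invasion_per_region(ext, partition = part)

      stage <- sprintf("ki67[%d]", i)
      kr <- ki67_ratio(tc$day14$dapi, tc$day14$ki67, part)

      stage <- sprintf("viability[%d]", i)
      vr <- viability(tc$day14$dapi, tc$day14$pi)

      metrics[[i]] <- rbind(
        data.frame(structure = i, region = gr$region, metric = "expansion_ratio",
                   value = gr$expansion_ratio),
        data.frame(structure = i, region = kr$region, metric = "ki67_ratio",
                   value = kr$ratio),
        data.frame(structure = i, region = ir$group,
                   metric = "normalized_invasion",
                   value = ir$normalized_invasion),
        data.frame(structure = i, region = "all", metric = "viability_percent",
                   value = vr$viability_percent))
    }
    stage <- "compare"
    metrics <- do.call(rbind, metrics)
    comparisons <- pipeline_comparisons(metrics)

    stage <- "write"
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
    manifest <- list(
      package = "bpq", version = as.character(packageVersion("bpq")),
      config = unclass(config),
      seeds = config$seed + seq_len(config$n_structures) - 1L,
      files = as.list(tools::md5sum(
        file.path(out_dir, c("metrics.csv", "comparisons.csv")))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("done")
    list(metrics = metrics, comparisons = comparisons, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage %s (out_dir %s): %s",
                 stage, out_dir, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

# paired tips-vs-trunk and stem-vs-branch-tip comparisons on the tidy table
pipeline_comparisons <- function(metrics) {
  rows <- list()
  for (m in c("expansion_ratio", "ki67_ratio", "normalized_invasion")) {
    d <- metrics[metrics$metric == m & metrics$region %in% c("tips", "trunk"), ]
    if (!nrow(d)) next
    wide <- merge(d[d$region == "tips", c("structure", "value")],
                  d[d$region == "trunk", c("structure", "value")],
                  by = "structure", suffixes = c("_tips", "_trunk"))
    if (nrow(wide) < 3L) next  # too few structures for any comparison
    r <- compare_groups(wide$value_tips, wide$value_trunk, paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, group_a = "tips", group_b = "trunk",
      mean_a = mean(wide$value_tips), mean_b = mean(wide$value_trunk),
      test = r$test_name, statistic = r$statistic, p_value = r$p_value,
      stars = r$stars, n = nrow(wide))
  }
  d <- metrics[metrics$metric == "ki67_ratio", ]
  stem <- d[d$region == "tip_stem", c("structure", "value")]
  br <- d[d$region %in% c("tip_left", "tip_right"), ]
  if (nrow(stem) >= 3 && nrow(br) >= 3) {
    brm <- stats::aggregate(value ~ structure, br, mean)
    wide <- merge(stem, brm, by = "structure", suffixes = c("_stem", "_branch"))
    r <- compare_groups(wide$value_stem, wide$value_branch, paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "ki67_ratio", group_a = "tip_stem", group_b = "branch_tips",
      mean_a = mean(wide$value_stem), mean_b = mean(wide$value_branch),
      test = r$test_name, statistic = r$statistic, p_value = r$p_value,
      stars = r$stars, n = nrow(wide))
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
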