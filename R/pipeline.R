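#' Pipeline run configuration
#'
#' Single configuration object driving the whole analysis:
#' simulate -> segment -> quantify -> quartiles -> stats. Stages are
#' individually toggleable so real (non-synthetic) acquisitions can enter
#' at the segmentation stage by placing TIFFs plus a `patients.csv` in
#' `paths$images`.
#'
#' @param outdir Root output directory of the run.
#' @param seed Integer seed; mandatory when the simulate stage is on.
#' @param stages Character vector of stages to execute.
#' @param cohort A [cohort_config()] (simulate stage).
#' @param field A [field_config()] (simulate stage).
#' @param segmentation A [segmentation_params()].
#' @param figures Write scatterplot SVGs with the stats stage.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       stages = c("simulate", "segment", "quantify",
                                  "quartiles", "stats"),
                       cohort = cohort_config(seed = seed),
                       field = field_config(),
                       segmentation = segmentation_params(),
                       figures = TRUE) {
  stopifnot(all(stages %in% c("simulate", "segment", "quantify",
                              "quartiles", "stats")))
  if ("simulate" %in% stages && is.null(seed))
    stop("seed is mandatory when the simulate stage is enabled")
  cohort$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 cohort = cohort, field = field, segmentation = segmentation,
                 figures = figures),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML override the package defaults of
#' [cohort_config()], [field_config()] and [segmentation_params()]; list
#' fields are matched by argument name.
#'
#' @param path YAML file with optional blocks `outdir`, `seed`, `stages`,
#'   `cohort`, `field`, `segmentation`, `figures`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, args %||% list())
  cohort <- build(cohort_config, y$cohort)
  run_config(outdir = y$outdir %||% ".",
             seed = y$seed %||% 1L,
             stages = y$stages %||% c("simulate", "segment", "quantify",
                                      "quartiles", "stats"),
             cohort = cohort,
             field = build(field_config, y$field),
             segmentation = build(segmentation_params, y$segmentation),
             figures = y$figures %||% TRUE)
}

stage_dir <- function(config, stage) {
  d <- file.path(config$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, fails fast on a stage error, and
#' writes a manifest listing every output file with its MD5 content hash.
#' Identical configuration and seed produce identical hashes for the
#' simulation-deterministic stages.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list: `seed`, per-stage `files` with hashes,
#'   `timings` (seconds per stage), `versions`, `timestamp`.
#' @export
run_all <- function(config) {
  stages <- config$stages
  out <- list(); timings <- c()
  files <- list()
  img_dir <- file.path(config$outdir, "images")
  lab_dir <- file.path(config$outdir, "labels")

  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    r
  }

  if ("simulate" %in% stages) {
    sim <- tick("simulate", generate_cohort(config$cohort, config$field,
                                            outdir = img_dir))
    files$simulate <- sim$files
  }

  meta_path <- file.path(img_dir, "patients.csv")
  if (!file.exists(meta_path))
    stop("missing input for downstream stages: ", meta_path,
         " (enable the simulate stage or provide real acquisitions)")
  metadata <- read.csv(meta_path, stringsAsFactors = FALSE)
  metadata$cad <- as.logical(metadata$cad)
  metadata$htn <- as.logical(metadata$htn)

  if ("segment" %in% stages) {
    dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
    tifs <- list.files(img_dir, pattern = "\\.tif$", full.names = TRUE)
    if (!length(tifs)) stop("no TIFF images found in ", img_dir)
    qc <- list()
    files$segment <- tick("segment", {
      unlist(lapply(tifs, function(tf) {
        stack <- read_image_stack(tf, config$field$pixel_size_um)
        lm_ <- segment_fibers(stack, config$segmentation)
        lp <- file.path(lab_dir, basename(tf))
        write_label_map(lm_, lp)
        qc[[basename(tf)]] <<- lm_$n_fibers
        lp
      }))
    })
    qc_path <- file.path(lab_dir, "segmentation_qc.json")
    jsonlite::write_json(qc, qc_path, auto_unbox = TRUE)
    files$segment <- c(files$segment, qc_path)
  }

  quant_dir <- file.path(config$outdir, "tables")
  fiber_path <- file.path(quant_dir, "fibers.csv")
  summary_path <- file.path(quant_dir, "specimen_summaries.csv")
  if ("quantify" %in% stages) {
    labs <- list.files(lab_dir, pattern = "\\.tif$", full.names = TRUE)
    if (!length(labs))
      stop("missing input: no label maps in ", lab_dir,
           " (run the segment stage first)")
    dir.create(quant_dir, recursive = TRUE, showWarnings = FALSE)
    res <- tick("quantify", {
      meas <- do.call(rbind, lapply(labs, function(lp) {
        stem <- sub("\\.tif$", "", basename(lp))
        pid <- sub("_f[0-9]+$", "", stem)
        fid <- sub("^.*_(f[0-9]+)$", "\\1", stem)
        stack <- read_image_stack(file.path(img_dir, basename(lp)),
                                  config$field$pixel_size_um)
        measure_field(stack, read_label_map(lp),
                      camera_black_gsu = config$field$camera_black_gsu,
                      patient_id = pid, field_id = fid)
      }))
      list(meas = meas, summaries = summarize_cohort(meas, metadata))
    })
    write.csv(res$meas, fiber_path, row.names = FALSE)
    write.csv(res$summaries, summary_path, row.names = FALSE)
    files$quantify <- c(fiber_path, summary_path)
  }

  quart_path <- file.path(quant_dir, "quartile_classes.csv")
  if ("quartiles" %in% stages) {
    if (!file.exists(fiber_path))
      stop("missing input: ", fiber_path, " (run the quantify stage first)")
    meas <- read.csv(fiber_path, stringsAsFactors = FALSE)
    qt <- tick("quartiles", quartile_table(meas, metadata))
    write.csv(qt, quart_path, row.names = FALSE)
    files$quartiles <- quart_path
  }

  if ("stats" %in% stages) {
    if (!file.exists(summary_path))
      stop("missing input: ", summary_path, " (run the quantify stage first)")
    if (!file.exists(quart_path))
      stop("missing input: ", quart_path, " (run the quartiles stage first)")
    summaries <- read.csv(summary_path, stringsAsFactors = FALSE)
    summaries$cad <- as.logical(summaries$cad)
    summaries$htn <- as.logical(summaries$htn)
    qt <- read.csv(quart_path, stringsAsFactors = FALSE)
    stats_dir <- stage_dir(config, "stats")
    res <- tick("stats", cohort_statistics(summaries, qt, metadata))
    json_path <- file.path(stats_dir, "results.json")
    jsonlite::write_json(strip_fits(res), json_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    txt_path <- file.path(stats_dir, "report.txt")
    write_stats_report(res, txt_path)
    files$stats <- c(json_path, txt_path)
    if (isTRUE(config$figures))
      files$stats <- c(files$stats,
                       plot_damage_relationships(summaries,
                                                 file.path(stats_dir, "figures")))
  }

  all_files <- unlist(files, use.names = FALSE)
  manifest <- list(
    seed = config$seed,
    stages = stages,
    files = data.frame(file = sub(paste0("^", config$outdir, "/?"), "",
                                  all_files),
                       md5 = unname(tools::md5sum(all_files)),
                       stringsAsFactors = FALSE),
    timings = as.list(timings),
    versions = list(fiberox = as.character(utils::packageVersion("fiberox")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  class(manifest) <- "run_manifest"
  manifest
}

strip_fits <- function(x) {
  if (is.list(x)) {
    x$fit <- NULL
    x <- lapply(x, function(e) if (is.list(e)) strip_fits(e) else e)
  }
  x
}

#' Cohort-level statistics bundle
#'
#' Runs every cohort analysis on specimen summaries and the quartile
#' table: adjusted group comparisons for all three outcomes, stage trend
#' and ABI partial correlation for both damage markers, repeated-measures
#' quartile models for both markers and groups, marker agreement across
#' PAD specimens, and the demographics table.
#'
#' @param summaries Specimen summary table.
#' @param quartile_tab Long quartile table with `group`.
#' @param metadata Patient metadata.
#' @return Nested list of result objects.
#' @export
cohort_statistics <- function(summaries, quartile_tab, metadata) {
  pad <- summaries[summaries$group == "pad", , drop = FALSE]
  # an analysis whose preconditions the cohort cannot meet (e.g. too few
  # PAD patients for a partial correlation) is reported as skipped, not
  # allowed to abort the remaining analyses
  attempt <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = conditionMessage(e)))
  list(
    group_comparison = lapply(setNames(nm = c("carbonyl", "hne", "csa")),
                              function(o) attempt(adjusted_group_comparison(summaries, o))),
    stage_trend = lapply(setNames(nm = c("carbonyl", "hne")),
                         function(o) attempt(stage_trend(pad, o))),
    abi_partial_correlation = lapply(setNames(nm = c("carbonyl", "hne")),
                                     function(o) attempt(abi_partial_correlation(pad, o))),
    quartile_models = lapply(setNames(nm = c("pad", "control")), function(g)
      lapply(setNames(nm = c("carbonyl", "hne")), function(m)
        attempt(quartile_repeated_measures(quartile_tab, m, g)))),
    marker_agreement = attempt(marker_agreement(pad)),
    demographics = attempt(
      demographics_table(metadata,
                         variables = intersect(c("abi", "cad", "htn"),
                                               names(metadata))))
  )
}

write_stats_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  skipped <- function(x, what) {
    if (!is.null(x$skipped)) {
      w("%s: skipped (%s)", what, x$skipped)
      TRUE
    } else FALSE
  }
  w("Cohort analysis report")
  w("======================")
  for (o in names(res$group_comparison)) {
    g <- res$group_comparison[[o]]
    if (skipped(g, paste(o, "group comparison"))) next
    w("%-8s adjusted means: control %.1f / PAD %.1f; %+.1f%% (vs larger), %+.1f%% (vs control); F(%d,%d)=%.2f p=%.3g",
      o, g$adjusted_mean_control, g$adjusted_mean_pad, g$percent_difference,
      g$percent_difference_vs_control, g$df[1], g$df[2], g$F_stat, g$p_value)
  }
  for (o in names(res$stage_trend)) {
    t <- res$stage_trend[[o]]
    if (skipped(t, paste(o, "stage trend"))) next
    w("%-8s vs stage: slope %.1f gsu/stage, R^2=%.2f, p=%.3g", o, t$slope,
      t$r_squared, t$p_value)
  }
  for (o in names(res$abi_partial_correlation)) {
    p <- res$abi_partial_correlation[[o]]
    if (skipped(p, paste(o, "ABI correlation"))) next
    w("%-8s vs ABI: partial r=%.2f [%.2f, %.2f], p=%.3g", o, p$r, p$ci_low,
      p$ci_high, p$p_value)
  }
  for (g in names(res$quartile_models)) for (m in names(res$quartile_models[[g]])) {
    q <- res$quartile_models[[g]][[m]]
    if (skipped(q, paste(g, m, "quartile model"))) next
    w("CSA by %s quartiles (%s): F(%d,%d)=%.2f p=%.3g; class means %s", m, g,
      q$df[1], q$df[2], q$overall_F, q$overall_p,
      paste(sprintf("%s=%.0f", names(q$class_means), q$class_means),
            collapse = " "))
    if (!is.null(q$contrasts))
      for (i in seq_len(nrow(q$contrasts)))
        w("  %s: %+.0f um^2, p=%.3g", q$contrasts$contrast[i],
          q$contrasts$estimate[i], q$contrasts$p_value[i])
  }
  if (!skipped(res$marker_agreement, "marker agreement"))
    w("marker agreement (PAD): r=%.2f, p=%.3g", res$marker_agreement$r,
      res$marker_agreement$p_value)
  invisible(path)
}

#' Validate an input dataset directory
#'
#' Checks the machine contract of a dataset: every TIFF has three pages
#' holding 12-bit data, `patients.csv` has the expected schema, every PAD
#' patient has an ABI, ground-truth/fiber CSVs (if present) have the
#' expected columns. Always returns a report; an empty `issues` data
#' frame means the dataset is well-formed.
#'
#' @param dir Dataset directory (images plus `patients.csv`).
#' @return Data frame with columns `file`, `issue`.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, issue)
    issues[[length(issues) + 1]] <<- data.frame(file = file, issue = issue,
                                                stringsAsFactors = FALSE)
  for (tf in list.files(dir, pattern = "\\.tif$", full.names = TRUE)) {
    pages <- tryCatch(tiff::readTIFF(tf, all = TRUE),
                      error = function(e) NULL)
    if (is.null(pages)) { note(basename(tf), "unreadable TIFF"); next }
    if (length(pages) != 3)
      note(basename(tf), sprintf("expected 3 channels, found %d", length(pages)))
    mx <- max(vapply(pages, max, numeric(1))) * 65535
    if (mx > GSU_MAX + 0.5)
      note(basename(tf), "pixel values exceed the 12-bit range")
  }
  meta_path <- file.path(dir, "patients.csv")
  if (!file.exists(meta_path)) {
    note("patients.csv", "missing metadata table")
  } else {
    md <- read.csv(meta_path, stringsAsFactors = FALSE)
    need <- c("patient_id", "group", "fontaine_stage", "abi", "cad", "htn")
    miss <- setdiff(need, names(md))
    if (length(miss))
      note("patients.csv", paste("missing columns:", paste(miss, collapse = ", ")))
    if (all(c("group", "abi", "patient_id") %in% names(md))) {
      bad <- md$patient_id[md$group == "pad" & is.na(md$abi)]
      for (b in bad) note("patients.csv", paste("missing ABI for PAD patient", b))
    }
  }
  gt_path <- file.path(dir, "ground_truth_fibers.csv")
  if (file.exists(gt_path)) {
    gt <- read.csv(gt_path, nrows = 1)
    need <- c("patient_id", "field_id", "fiber_id", "true_csa_um2",
              "true_carbonyl_gsu", "true_hne_gsu")
    miss <- setdiff(need, names(gt))
    if (length(miss))
      note("ground_truth_fibers.csv",
           paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (!length(issues))
    return(data.frame(file = character(), issue = character()))
  do.call(rbind, issues)
}
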