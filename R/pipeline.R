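#' Demo pipeline configuration
#'
#' A compressed version of the full 21-day design that exercises every stage
#' quickly: the four study conditions, 2 replicates x 4 fields of view, a
#' 48-hour schedule with a dense-then-sparse cadence, and a 256 px field at
#' 2 um/px. Intended for examples, smoke tests and determinism checks.
#'
#' @param seed integer seed recorded in the config.
#' @return a pipeline config list (see [run_pipeline()]).
#' @export
demo_config <- function(seed = 1) {
  list(seed = seed,
       conditions = default_conditions(n_cells_per_fov = 8),
       schedule_phases = list(c(0, 6, 3), c(6, 48, 7)),
       n_replicates = 2, n_fovs = 4,
       geometry = frame_geometry(256, 256, 2),
       segmentation = segmentation_config(smooth_sigma_px = 1,
                                          min_area_px = 20),
       fft = list(n_bins = 180),
       divergence = list(alpha = 0.05, persistence_k = 1, mode = "anova"),
       ddct = NULL)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Condition entries are passed to [condition_params()], `schedule_phases`
#' to [make_schedule()], `geometry` to [frame_geometry()] and `segmentation`
#' to [segmentation_config()]; anything omitted falls back to the demo
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return pipeline config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- demo_config()
  for (nm in intersect(names(raw), c("seed", "n_replicates", "n_fovs")))
    cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$schedule_phases))
    cfg$schedule_phases <- lapply(raw$schedule_phases, as.numeric)
  if (!is.null(raw$geometry))
    cfg$geometry <- do.call(frame_geometry, raw$geometry)
  if (!is.null(raw$segmentation))
    cfg$segmentation <- do.call(segmentation_config, raw$segmentation)
  if (!is.null(raw$conditions))
    cfg$conditions <- lapply(raw$conditions, function(cc) do.call(condition_params, cc))
  if (!is.null(raw$fft)) cfg$fft <- raw$fft
  if (!is.null(raw$divergence)) cfg$divergence <- raw$divergence
  if (!is.null(raw$ddct)) cfg$ddct <- raw$ddct
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
      file = log_path, append = TRUE)
  invisible(msg)
}

#' Read and validate a manifest CSV
#'
#' @param path manifest file written by [simulate_experiment()].
#' @param check_files verify that every referenced frame exists.
#' @return validated data.frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  mf <- read_table_csv(path, required = c("path", "condition", "replicate",
                                          "fov", "timestamp_h"))
  key <- paste(mf$condition, mf$replicate, mf$fov)
  for (g in unique(key)) {
    ts <- mf$timestamp_h[key == g]
    if (any(diff(ts) <= 0))
      stop(sprintf("manifest timestamps for %s are not strictly increasing", g))
  }
  if (check_files) {
    full <- file.path(dirname(path), mf$path)
    missing <- which(!file.exists(full))
    if (length(missing))
      stop(sprintf("manifest row %d: frame file missing (%s)",
                   missing[1], mf$path[missing[1]]))
  }
  mf
}

#' Read a CSV table with strict schema validation
#'
#' C-locale dialect only: comma separator, '.' decimal, mandatory header.
#' Numeric columns containing locale decimal commas are rejected with the
#' offending line number.
#'
#' @param path CSV file.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as numeric.
#' @return data.frame.
#' @export
read_table_csv <- function(path, required = character(0),
                           numeric_cols = intersect(required,
                                                    c("timestamp_h", "replicate",
                                                      "ct_value", "area_um2"))) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  for (col in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad))
        stop(sprintf("%s: column '%s' is not numeric at data line %d (value '%s'); use '.' as the decimal separator",
                     basename(path), col, bad[1], df[[col]][bad[1]]))
      df[[col]] <- num
    }
  }
  df
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> segment -> measure -> align -> diverge (-> ddct when
#' a Ct table is configured) and writes every artifact under `out_dir`:
#' `frames/`, `masks/` (truth), `masks_pred/`, `manifest.csv`, `truth.csv`,
#' `shapes.csv`, `qc_counts.csv`, `spectra.csv`, `surface_<condition>.csv`,
#' `table1.csv`, optionally `expression.csv`, and `run.log` with per-stage
#' timings, object counts, the seed and a config hash. The run is a
#' deterministic function of the config (including its seed).
#'
#' @param config pipeline config list ([demo_config()],
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created).
#' @return invisibly, a list with the main tables (`shapes`, `table1`,
#'   `spectra`, `expression`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line(log_path, "pipeline start: seed=%d config_hash=%s version=%s",
           config$seed, config_hash(config),
           as.character(utils::packageVersion("topomorph")))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    log_line(log_path, "stage %-8s done in %.1f s", name,
             proc.time()[["elapsed"]] - t0)
    res
  }

  sched <- make_schedule(config$schedule_phases)
  sim <- stage("simulate",
               simulate_experiment(config$conditions, sched,
                                   n_replicates = config$n_replicates,
                                   n_fovs = config$n_fovs,
                                   geometry = config$geometry,
                                   rng_seed = config$seed,
                                   out_dir = out_dir))
  mf <- sim$manifest

  dir.create(file.path(out_dir, "masks_pred"), showWarnings = FALSE)
  seg_out <- stage("segment", {
    qc <- vector("list", nrow(mf))
    for (i in seq_len(nrow(mf))) {
      img <- read_frame_tiff(file.path(out_dir, mf$path[i]))
      sm <- segment_frame(img, config$segmentation)
      mp <- file.path("masks_pred", basename(mf$mask_path[i]))
      write_mask_tiff(sm$labels, file.path(out_dir, mp))
      qc[[i]] <- data.frame(path = mf$path[i], mask_pred_path = mp,
                            condition = mf$condition[i],
                            replicate = mf$replicate[i], fov = mf$fov[i],
                            timestamp_h = mf$timestamp_h[i],
                            n_objects = sm$n_objects,
                            degenerate = sm$degenerate)
    }
    do.call(rbind, qc)
  })
  utils::write.csv(seg_out, file.path(out_dir, "qc_counts.csv"), row.names = FALSE)
  log_line(log_path, "segmented %d frames, %d objects total",
           nrow(seg_out), sum(seg_out$n_objects))

  shapes <- stage("measure", {
    rows <- vector("list", nrow(seg_out))
    for (i in seq_len(nrow(seg_out))) {
      lab <- read_mask_tiff(file.path(out_dir, seg_out$mask_pred_path[i]))
      rows[[i]] <- measure_objects(lab, config$geometry$pixel_size_um,
                                   metadata = list(
                                     condition = seg_out$condition[i],
                                     replicate = seg_out$replicate[i],
                                     fov_id = seg_out$fov[i],
                                     timestamp_h = seg_out$timestamp_h[i]))
    }
    do.call(rbind, rows)
  })
  utils::write.csv(shapes, file.path(out_dir, "shapes.csv"), row.names = FALSE)
  log_line(log_path, "measured %d objects", nrow(shapes))

  spectra_tbl <- stage("align", {
    n_bins <- config$fft$n_bins %||% 180
    out <- list(); k <- 0L
    for (cond in unique(mf$condition)) {
      per_time <- list()
      for (t in sort(unique(mf$timestamp_h))) {
        sel <- which(mf$condition == cond & mf$timestamp_h == t)
        sp <- lapply(sel, function(i)
          angular_power_sum(read_frame_tiff(file.path(out_dir, mf$path[i])),
                            n_bins = n_bins))
        comb <- combine_and_normalize(sp)
        comb$condition <- cond; comb$timestamp_h <- t
        per_time[[length(per_time) + 1L]] <- comb
        k <- k + 1L
        out[[k]] <- data.frame(condition = cond, timestamp_h = t,
                               angle_deg = comb$angles_deg,
                               magnitude = comb$magnitude,
                               n_fovs = comb$n_fovs_combined)
      }
      surf <- build_time_angle_surface(per_time, schedule = sched$timestamps_h)
      sm <- cbind(data.frame(timestamp_h = surf$timestamps_h,
                             peak_deg = surf$peak_deg),
                  as.data.frame(surf$surface))
      names(sm)[-(1:2)] <- sprintf("a%g", surf$angles_deg)
      utils::write.csv(sm, file.path(out_dir, sprintf("surface_%s.csv", cond)),
                       row.names = FALSE)
    }
    do.call(rbind, out)
  })
  utils::write.csv(spectra_tbl, file.path(out_dir, "spectra.csv"),
                   row.names = FALSE)

  conds <- vapply(config$conditions, `[[`, character(1), "name")
  study_pairs <- list(c("flat", "flat-osteo"), c("flat", "aligned"),
                      c("random", "flat"), c("aligned", "random"))
  pairs <- config$divergence$pairs %||%
    (if (all(unique(unlist(study_pairs)) %in% conds)) study_pairs
     else utils::combn(conds, 2, simplify = FALSE))
  table1 <- stage("diverge",
                  divergence_table(shapes, pairs = pairs,
                                   alpha = config$divergence$alpha %||% 0.05,
                                   persistence_k = config$divergence$persistence_k %||% 1,
                                   mode = config$divergence$mode %||% "anova"))
  utils::write.csv(table1, file.path(out_dir, "table1.csv"), row.names = FALSE)

  expression <- NULL
  if (!is.null(config$ddct)) {
    ct <- read_table_csv(config$ddct$ct_table,
                         required = c("sample_id", "condition", "gene",
                                      "ct_value", "replicate"))
    expression <- stage("ddct",
                        ddct_analysis(ct, housekeeping = config$ddct$housekeeping,
                                      calibrator = config$ddct$calibrator,
                                      log_base = config$ddct$log_base %||% 2))
    utils::write.csv(expression, file.path(out_dir, "expression.csv"),
                     row.names = FALSE)
  }
  log_line(log_path, "pipeline done")
  invisible(list(shapes = shapes, table1 = table1, spectra = spectra_tbl,
                 expression = expression, out_dir = out_dir))
}
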