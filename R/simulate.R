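#' Exact perimeter of an ellipse (Ramanujan's second approximation)
#'
#' Used for ground-truth shape records; accurate to well below 0.01% for the
#' aspect ratios rendered here.
#'
#' @param a,b semi-axes.
#' @return perimeter, same units as the axes.
#' @keywords internal
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

truth_records <- function(cells, condition, replicate, fov_id, timestamp_h) {
  a <- cells$semi_major_um
  b <- cells$semi_minor_um
  area <- pi * a * b
  perim <- ellipse_perimeter(a, b)
  data.frame(object_id = cells$cell_id,
             condition = condition,
             replicate = replicate,
             fov_id = fov_id,
             timestamp_h = timestamp_h,
             area_um2 = area,
             perimeter_um = perim,
             circularity = pmin(1, 4 * pi * area / perim^2),
             major_axis_um = 2 * a,
             minor_axis_um = 2 * b,
             orientation_deg = cells$orientation_deg)
}

#' Simulate a complete time-lapse experiment
#'
#' Runs the full acquisition design: for every condition, replicate and field
#' of view a cell population is sampled once, then grown along the
#' condition's spreading trajectory and rendered at every schedule timestamp.
#' Ground truth (label masks and analytic shape records of the generative
#' ellipses) is emitted alongside every frame, so every downstream stage can
#' be validated without experimental data.
#'
#' With `out_dir` set, frames and masks are written as single-channel 16-bit
#' TIFFs plus a `manifest.csv` (`path, mask_path, condition, replicate, fov,
#' timestamp_h`) and a `truth.csv` of the shape records; only the tables are
#' kept in memory. Without it, everything (including frames) is returned.
#'
#' @param conditions list of [condition_params()] (e.g. [default_conditions()]).
#' @param schedule an [make_schedule()] result, or numeric vector of hours.
#' @param n_replicates,n_fovs acquisition design (the study design is 2
#'   replicates with 4 fields of view per substrate).
#' @param geometry a [frame_geometry()].
#' @param rng_seed integer seed; the whole simulation is a deterministic
#'   function of it.
#' @param out_dir optional output directory for TIFFs and CSVs.
#' @return list with `truth` (data.frame), `manifest` (data.frame or NULL),
#'   `frames` (list of `frame_image`, NULL when writing to disk), `schedule`,
#'   `rng_seed`.
#' @export
simulate_experiment <- function(conditions, schedule, n_replicates = 2,
                                n_fovs = 4,
                                geometry = frame_geometry(512, 512, 1),
                                rng_seed = 1, out_dir = NULL) {
  ts <- if (inherits(schedule, "acquisition_schedule")) schedule$timestamps_h
        else as.numeric(schedule)
  set.seed(rng_seed)
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  fov_um <- c(geometry$width_px, geometry$height_px) * geometry$pixel_size_um
  truth <- list(); manifest <- list(); frames <- list()
  k <- 0L
  for (cond in conditions) {
    for (rep_i in seq_len(n_replicates)) {
      for (fov_i in seq_len(n_fovs)) {
        fov_id <- sprintf("r%df%d", rep_i, fov_i)
        pop <- sample_population(cond, fov_um = fov_um)
        for (t in ts) {
          k <- k + 1L
          cells <- grow_population(pop, t, cond)
          fr <- render_frame(cells, geometry, noise = cond$noise,
                             timestamp_h = t, condition = cond$name,
                             fov_id = fov_id)
          truth[[k]] <- truth_records(cells, cond$name, rep_i, fov_id, t)
          if (write_out) {
            stub <- sprintf("%s_%s_t%08.2fh", cond$name, fov_id, t)
            fp <- file.path("frames", paste0(stub, ".tif"))
            mp <- file.path("masks", paste0(stub, "_mask.tif"))
            write_frame_tiff(fr$pixels, file.path(out_dir, fp))
            write_mask_tiff(fr$mask, file.path(out_dir, mp))
            manifest[[k]] <- data.frame(path = fp, mask_path = mp,
                                        condition = cond$name,
                                        replicate = rep_i, fov = fov_id,
                                        timestamp_h = t,
                                        pixel_size_um = geometry$pixel_size_um)
          } else {
            frames[[k]] <- fr
          }
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  manifest <- if (write_out) do.call(rbind, manifest) else NULL
  if (write_out) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(truth = truth, manifest = manifest,
       frames = if (write_out) NULL else frames,
       schedule = ts, rng_seed = rng_seed)
}

#' Write a single-channel frame as 16-bit TIFF
#' @param pixels matrix with values in `[0, 1]`.
#' @param path output file.
#' @keywords internal
write_frame_tiff <- function(pixels, path) {
  tiff::writeTIFF(pixels, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a label mask as 16-bit TIFF (labels scaled by 1/65535)
#' @param mask integer matrix, 0 = background.
#' @param path output file.
#' @keywords internal
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored in a 16-bit mask")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a frame TIFF back as an intensity matrix in `[0, 1]`
#' @param path file path.
#' @export
read_frame_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Read a label-mask TIFF back as an integer label matrix
#' @param path file path.
#' @export
read_mask_tiff <- function(path) {
  m <- read_frame_tiff(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
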