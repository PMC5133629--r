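#' Segmentation configuration
#'
#' Parameters of the transparent threshold-based segmentation stage:
#' Gaussian smooth, global threshold (Otsu or fixed), hole filling, small
#' object removal, optional border clearing, connected-component labelling.
#'
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels (0 = none).
#' @param threshold_method `"otsu"` (global, data-driven) or `"fixed"`.
#' @param threshold fixed threshold in intensity units, used when
#'   `threshold_method = "fixed"`.
#' @param min_area_px objects smaller than this many pixels are dropped.
#' @param clear_border drop objects touching the frame border.
#' @param connectivity 4 or 8 (default) pixel connectivity; recorded on the
#'   output mask.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(smooth_sigma_px = 1,
                                threshold_method = c("otsu", "fixed"),
                                threshold = 0.5,
                                min_area_px = 50,
                                clear_border = FALSE,
                                connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_area_px >= 1, smooth_sigma_px >= 0,
            connectivity %in% c(4, 8))
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 threshold_method = threshold_method,
                 threshold = threshold,
                 min_area_px = as.integer(min_area_px),
                 clear_border = isTRUE(clear_border),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

# Connected-component labelling at the requested connectivity.
# EBImage::bwlabel is 4-connected; for 8-connectivity, labels that touch
# diagonally are merged afterwards with a union-find pass on the label graph.
label_components <- function(bw, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # SE diagonal
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # SW diagonal
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      remap <- c(0L, match(root, sort(unique(root))))
      lab <- matrix(remap[lab + 1L], nr, nc)
    }
  }
  lab
}

# Renumber labels 1..n in order of first (column-major) appearance.
compact_labels <- function(lab) {
  u <- unique(as.vector(lab))
  u <- u[u > 0L]
  if (length(u) == 0L) return(lab)
  remap <- integer(max(lab) + 1L)
  remap[u + 1L] <- seq_along(u)
  matrix(remap[lab + 1L], nrow(lab), ncol(lab))
}

#' Segment a fluorescent frame into labelled objects
#'
#' Pipeline: Gaussian smooth, global threshold (Otsu by default), fill holes,
#' remove objects below `min_area_px`, optionally remove border-touching
#' objects, connected-component labelling. Fully deterministic.
#'
#' A constant (featureless) image under Otsu thresholding yields an empty
#' mask with `degenerate = TRUE` rather than an error, so blank frames at
#' the start of an acquisition do not halt a run.
#'
#' @param image a `frame_image`, or a plain numeric matrix of intensities.
#' @param config a [segmentation_config()].
#' @return object of class `label_mask`: list with `labels` (integer matrix,
#'   0 = background), `n_objects`, `connectivity`, `frame_ref`, `degenerate`.
#' @export
segment_frame <- function(image, config = segmentation_config()) {
  pix <- if (inherits(image, "frame_image")) image$pixels else image
  if (!is.matrix(pix)) stop("`image` must be a matrix or frame_image")
  if (any(!is.finite(pix)) || any(pix < 0))
    stop("image must be finite and non-negative")
  frame_ref <- if (inherits(image, "frame_image"))
    sprintf("%s/%s@%gh", image$condition, image$fov_id, image$timestamp_h)
  else NA_character_
  sm <- pix
  if (config$smooth_sigma_px > 0)
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(pix),
                                            sigma = config$smooth_sigma_px))
  degenerate <- FALSE
  if (config$threshold_method == "otsu") {
    rng <- range(sm)
    if (diff(rng) < 1e-12) {
      degenerate <- TRUE
      bw <- matrix(FALSE, nrow(sm), ncol(sm))
    } else {
      sc <- (sm - rng[1]) / diff(rng)
      thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
      bw <- sc > thr
    }
  } else {
    bw <- sm > config$threshold
  }
  if (!degenerate && any(bw)) {
    bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
    lab <- label_components(bw, config$connectivity)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < config$min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    if (config$clear_border) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      border <- border[border > 0L]
      if (length(border)) lab[lab %in% border] <- 0L
    }
    lab <- compact_labels(lab)
  } else {
    lab <- matrix(0L, nrow(sm), ncol(sm))
  }
  structure(list(labels = lab, n_objects = max(lab),
                 connectivity = config$connectivity,
                 frame_ref = frame_ref, degenerate = degenerate),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label mask (%s): %d object(s), %d-connectivity%s\n",
              x$frame_ref, x$n_objects, x$connectivity,
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

as_label_matrix <- function(x) {
  if (inherits(x, "label_mask")) x$labels
  else if (is.matrix(x)) matrix(as.integer(x), nrow(x), ncol(x))
  else stop("expected a label_mask or integer matrix")
}

#' Compare a predicted segmentation with ground truth
#'
#' Matches predicted objects to truth objects greedily by maximal pixel
#' overlap (one-to-one), reports the intersection-over-union (IoU) for every
#' matched pair, and lists unmatched objects on both sides. The comparison is
#' invariant to label renumbering of either mask. This is the automated
#' stand-in for manual-versus-automated segmentation validation.
#'
#' @param predicted,truth `label_mask` objects or integer label matrices of
#'   identical dimensions.
#' @return list with `matches` (data.frame: `truth_label`, `pred_label`,
#'   `overlap_px`, `iou`), `unmatched_truth`, `unmatched_pred`,
#'   `count_diff` (predicted minus truth object count), `mean_iou`.
#' @export
validate_segmentation <- function(predicted, truth) {
  p <- as_label_matrix(predicted)
  t <- as_label_matrix(truth)
  if (!all(dim(p) == dim(t))) stop("mask dimensions differ")
  p_sizes <- tabulate(p[p > 0L])
  t_sizes <- tabulate(t[t > 0L])
  p_ids <- which(p_sizes > 0L)
  t_ids <- which(t_sizes > 0L)
  both <- p > 0L & t > 0L
  matches <- data.frame(truth_label = integer(0), pred_label = integer(0),
                        overlap_px = integer(0), iou = numeric(0))
  if (any(both)) {
    ov <- table(truth_label = t[both], pred_label = p[both])
    ov_df <- as.data.frame(ov, stringsAsFactors = FALSE)
    ov_df <- ov_df[ov_df$Freq > 0L, ]
    ov_df$truth_label <- as.integer(ov_df$truth_label)
    ov_df$pred_label <- as.integer(ov_df$pred_label)
    ov_df <- ov_df[order(-ov_df$Freq), ]
    used_t <- used_p <- integer(0)
    for (r in seq_len(nrow(ov_df))) {
      tl <- ov_df$truth_label[r]; pl <- ov_df$pred_label[r]
      if (tl %in% used_t || pl %in% used_p) next
      inter <- ov_df$Freq[r]
      uni <- t_sizes[tl] + p_sizes[pl] - inter
      matches <- rbind(matches, data.frame(truth_label = tl, pred_label = pl,
                                           overlap_px = inter,
                                           iou = inter / uni))
      used_t <- c(used_t, tl); used_p <- c(used_p, pl)
    }
  }
  list(matches = matches,
       unmatched_truth = setdiff(t_ids, matches$truth_label),
       unmatched_pred = setdiff(p_ids, matches$pred_label),
       count_diff = length(p_ids) - length(t_ids),
       mean_iou = if (nrow(matches)) mean(matches$iou) else NA_real_)
}
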