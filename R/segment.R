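#' Segmentation parameters
#'
#' Controls for membrane-based fiber segmentation: pre-smoothing of the
#' membrane channel, the membrane threshold (Otsu by default), the
#' physical size window of plausible fibers, and exclusion of fibers
#' touching the image border (whose cross-sectional area is truncated and
#' would bias morphometry).
#'
#' @param smooth_sigma_px Gaussian smoothing sigma applied to the membrane
#'   channel before thresholding; 0 disables it.
#' @param membrane_threshold `"otsu"` or `"fixed"`.
#' @param fixed_threshold_gsu Threshold in gsu when
#'   `membrane_threshold = "fixed"`.
#' @param min_fiber_area_um2,max_fiber_area_um2 Area window outside which
#'   detected regions are discarded. The defaults bracket the adult human
#'   myofiber CSA range with wide margins.
#' @param exclude_edge_fibers Drop regions touching the image border.
#' @param closing_radius_px Radius of the morphological closing applied to
#'   the membrane mask (bridges small gaps in the rim).
#' @param watershed Apply a distance-map watershed refinement to split
#'   touching interiors; useful on noisy membranes, off by default.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smooth_sigma_px = 1,
                                membrane_threshold = c("otsu", "fixed"),
                                fixed_threshold_gsu = NULL,
                                min_fiber_area_um2 = 200,
                                max_fiber_area_um2 = 20000,
                                exclude_edge_fibers = TRUE,
                                closing_radius_px = 1,
                                watershed = FALSE) {
  membrane_threshold <- match.arg(membrane_threshold)
  if (membrane_threshold == "fixed" && is.null(fixed_threshold_gsu))
    stop("fixed_threshold_gsu required when membrane_threshold = 'fixed'")
  stopifnot(smooth_sigma_px >= 0,
            min_fiber_area_um2 > 0,
            max_fiber_area_um2 > min_fiber_area_um2)
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 membrane_threshold = membrane_threshold,
                 fixed_threshold_gsu = fixed_threshold_gsu,
                 min_fiber_area_um2 = min_fiber_area_um2,
                 max_fiber_area_um2 = max_fiber_area_um2,
                 exclude_edge_fibers = exclude_edge_fibers,
                 closing_radius_px = closing_radius_px,
                 watershed = watershed),
            class = "segmentation_params")
}

#' Label map of segmented fibers
#'
#' @param labels Non-negative integer matrix; 0 is the
#'   extracellular/background compartment, 1..n_fibers are fiber
#'   interiors, consecutively numbered.
#' @param excluded_labels Integer vector of pre-relabeling region ids
#'   removed by edge/size filtering (diagnostic).
#' @param membrane_mask Optional logical matrix marking the pixels the
#'   segmentation classified as membrane/extracellular rim. When present,
#'   background estimation uses this mask rather than all label-0 pixels
#'   (label 0 also covers filtered-out fiber interiors, which carry
#'   intracellular signal and would inflate the background).
#' @return A `label_map` object with fields `labels`, `n_fibers`,
#'   `excluded_labels`, `membrane_mask`.
#' @export
label_map <- function(labels, excluded_labels = integer(),
                      membrane_mask = NULL) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0]))
  if (length(u) && !identical(u, seq_along(u)))
    stop("fiber labels must be consecutive 1..n_fibers")
  structure(list(labels = labels, n_fibers = length(u),
                 excluded_labels = excluded_labels,
                 membrane_mask = membrane_mask),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d fibers (%d regions excluded)\n",
              nrow(x$labels), ncol(x$labels), x$n_fibers,
              length(x$excluded_labels)))
  invisible(x)
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  out
}

#' Segment myofibers from the membrane channel
#'
#' Partitions a field into individual fibers using the sarcolemmal
#' (membrane) stain: Gaussian smoothing, membrane thresholding (Otsu by
#' default), morphological closing of the membrane mask, connected
#' components of the mask complement, then size and border filtering.
#' Fiber labels never overlap pixels classified as membrane.
#'
#' @param stack An [image_stack()].
#' @param params A [segmentation_params()].
#' @return A [label_map()]. Zero surviving fibers yields an empty label
#'   map with a warning, not an error.
#' @export
segment_fibers <- function(stack, params = segmentation_params()) {
  m <- stack$membrane
  if (max(m) == min(m)) stop("no membrane structure: constant membrane channel")
  mn <- m / GSU_MAX
  if (params$smooth_sigma_px > 0)
    mn <- as.matrix(EBImage::gblur(mn, sigma = params$smooth_sigma_px))
  thr <- if (params$membrane_threshold == "otsu") {
    EBImage::otsu(EBImage::Image(mn), range = range(mn))
  } else {
    params$fixed_threshold_gsu / GSU_MAX
  }
  mask <- mn > thr
  if (params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius_px + 1, "diamond")
    mask <- EBImage::closing(mask, brush) > 0
  }
  interiors <- !mask
  if (params$watershed) {
    dm <- EBImage::distmap(interiors)
    lab <- EBImage::imageData(EBImage::watershed(dm))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(interiors))
  }
  storage.mode(lab) <- "integer"
  lab[mask] <- 0L

  px_um2 <- stack$pixel_size_um^2
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes * px_um2 < params$min_fiber_area_um2 |
                sizes * px_um2 > params$max_fiber_area_um2)
  if (params$exclude_edge_fibers) {
    h <- nrow(lab); w <- ncol(lab)
    border <- c(lab[1, ], lab[h, ], lab[, 1], lab[, w])
    drop <- union(drop, unique(border[border > 0]))
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  out <- label_map(relabel_consecutive(lab), excluded_labels = sort(drop),
                   membrane_mask = mask)
  if (out$n_fibers == 0)
    warning("no fibers survived segmentation filtering")
  out
}

#' Match a segmentation to ground truth
#'
#' Greedy one-to-one matching of detected fibers to ground-truth fibers by
#' descending intersection-over-union (IoU); a pair matches iff
#' IoU >= 0.5. Reports instance precision and recall and the median
#' absolute relative area error over matched pairs. Invariant to label
#' permutations of either input.
#'
#' @param label_map A [label_map()] (or integer matrix) of detections.
#' @param truth_labels Ground-truth labels, same dimensions.
#' @param iou_threshold Minimum IoU for a match.
#' @return A `match_report` list: `n_true`, `n_detected`, `n_matched`,
#'   `precision`, `recall`, `median_abs_relative_area_error`, and the
#'   per-pair `matches` data frame.
#' @export
match_to_ground_truth <- function(label_map, truth_labels, iou_threshold = 0.5) {
  det <- if (inherits(label_map, "label_map")) label_map$labels else label_map
  tru <- if (inherits(truth_labels, "label_map")) truth_labels$labels else truth_labels
  if (!identical(dim(det), dim(tru))) stop("dimension mismatch")

  det_ids <- sort(unique(det[det > 0]))
  tru_ids <- sort(unique(tru[tru > 0]))
  n_det <- length(det_ids); n_tru <- length(tru_ids)

  both <- det > 0 & tru > 0
  matches <- data.frame(truth_id = integer(), det_id = integer(),
                        iou = numeric(), rel_area_error = numeric())
  if (any(both) && n_det && n_tru) {
    ov <- table(truth = tru[both], det = det[both])
    tru_sz <- tabulate(tru[tru > 0])
    det_sz <- tabulate(det[det > 0])
    pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0, ]
    ti <- as.integer(pairs$truth); di <- as.integer(pairs$det)
    inter <- pairs$Freq
    iou <- inter / (tru_sz[ti] + det_sz[di] - inter)
    ord <- order(iou, decreasing = TRUE)
    used_t <- logical(max(ti)); used_d <- logical(max(di))
    keep <- list()
    for (k in ord) {
      if (iou[k] < iou_threshold) break
      if (used_t[ti[k]] || used_d[di[k]]) next
      used_t[ti[k]] <- TRUE; used_d[di[k]] <- TRUE
      keep[[length(keep) + 1]] <- data.frame(
        truth_id = ti[k], det_id = di[k], iou = iou[k],
        rel_area_error = abs(det_sz[di[k]] - tru_sz[ti[k]]) / tru_sz[ti[k]])
    }
    if (length(keep)) matches <- do.call(rbind, keep)
  }
  n_matched <- nrow(matches)
  structure(list(
    n_true = n_tru, n_detected = n_det, n_matched = n_matched,
    precision = if (n_det) n_matched / n_det else NA_real_,
    recall = if (n_tru) n_matched / n_tru else NA_real_,
    median_abs_relative_area_error =
      if (n_matched) median(matches$rel_area_error) else NA_real_,
    matches = matches
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(paste0("match_report: %d true, %d detected, %d matched ",
                     "(precision %.3f, recall %.3f, median |area err| %.3f)\n"),
              x$n_true, x$n_detected, x$n_matched,
              x$precision, x$recall, x$median_abs_relative_area_error))
  invisible(x)
}
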