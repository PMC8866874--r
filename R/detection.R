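# Single-instance eardrum detection: geometry (bounding boxes, IoU), the
# joint classification + localization loss, the IoU-thresholded accuracy
# protocol, and patch extraction for the downstream embedder.

#' Axis-aligned bounding box in normalized coordinates
#'
#' Coordinates run in \[0,1\], x to the right, y down; the box spans
#' `[x_min, x_max] x [y_min, y_max]` inclusively.
#'
#' @param x_min,y_min,x_max,y_max corner coordinates, with
#'   `x_min < x_max` and `y_min < y_max`.
#' @return an object of class `scad_box` (named numeric length 4).
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (anyNA(b) || any(!is.finite(b))) stop_numeric("box coordinates must be finite")
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"]) {
    stop_spec("bounding box requires x_min < x_max and y_min < y_max")
  }
  class(b) <- "scad_box"
  b
}

as_box <- function(b) {
  if (inherits(b, "scad_box")) return(b)
  if (is.numeric(b) && length(b) == 4L) {
    return(bounding_box(b[[1]], b[[2]], b[[3]], b[[4]]))
  }
  stop_spec("cannot interpret object as a bounding box")
}

box_area <- function(b) (b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]])

#' Intersection over union of two boxes
#'
#' Computed analytically on continuous normalized coordinates.
#'
#' @param a,b bounding boxes ([bounding_box()] or numeric
#'   `c(x_min, y_min, x_max, y_max)`).
#' @return overlap ratio in \[0, 1\].
#' @examples
#' iou(c(0, 0, 1, 1), c(0, 0, 0.5, 1))  # 0.5
#' @export
iou <- function(a, b) {
  a <- as_box(a)
  b <- as_box(b)
  if (box_area(a) <= 0 || box_area(b) <= 0) stop_spec("degenerate (zero-area) box")
  ix <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  iy <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  inter <- max(0, ix) * max(0, iy)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Joint detection loss: cross entropy plus masked box L1
#'
#' The classification term is the cross entropy of the true eardrum-present
#' label under the predicted class probability. The localization term is the
#' mean absolute difference over the four normalized box coordinates and is
#' included only for frames that truly show the eardrum (an L1 distance to an
#' undefined box is meaningless, so it is masked on negative frames).
#'
#' @param pred list with `class_prob` (probability the frame shows an eardrum;
#'   alternatively a length-2 vector `(p_negative, p_positive)`) and `box`
#'   (predicted box; may be `NULL` for negative frames).
#' @param truth a frame record (fields `has_eardrum` and `box`).
#' @return non-negative scalar loss.
#' @examples
#' fr <- list(has_eardrum = TRUE, box = bounding_box(0.2, 0.2, 0.8, 0.8))
#' detection_loss(list(class_prob = 0.5, box = fr$box), fr)  # log(2)
#' @export
detection_loss <- function(pred, truth) {
  p <- pred$class_prob
  if (length(p) == 2L) p <- p[[2]]
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop_numeric("`class_prob` must be a finite probability")
  }
  p_true <- if (isTRUE(truth$has_eardrum)) p else 1 - p
  l_cls <- -log(max(p_true, .Machine$double.xmin))
  l_loc <- 0
  if (isTRUE(truth$has_eardrum)) {
    if (is.null(truth$box)) stop_spec("positive frame is missing its ground-truth box")
    if (is.null(pred$box)) stop_spec("positive frame needs a predicted box")
    pb <- as_box(pred$box)
    tb <- as_box(truth$box)
    if (any(!is.finite(pb))) stop_numeric("non-finite predicted box")
    l_loc <- mean(abs(as.numeric(pb) - as.numeric(tb)))
  }
  l_cls + l_loc
}

#' IoU-thresholded detection accuracy
#'
#' A frame counts as correct iff its hard classification
#' (`class_score >= class_threshold`) matches the ground-truth eardrum flag
#' and, when both ground truth and classification are positive, the predicted
#' box overlaps the true box with IoU strictly greater than `iou_threshold`.
#'
#' @param preds list of detection outputs (`class_score`, `box`), one per frame.
#' @param truths list of frame records of equal length.
#' @param iou_threshold IoU cutoff (default 0.5).
#' @param class_threshold classification cutoff (default 0.5).
#' @return accuracy as a percentage in \[0, 100\].
#' @export
evaluate_detection <- function(preds, truths, iou_threshold = 0.5,
                               class_threshold = 0.5) {
  if (length(preds) == 0L || length(preds) != length(truths)) {
    stop_spec("`preds` and `truths` must be non-empty lists of equal length")
  }
  correct <- vapply(seq_along(preds), function(i) {
    pr <- preds[[i]]
    tr <- truths[[i]]
    cls_pos <- pr$class_score >= class_threshold
    if (cls_pos != isTRUE(tr$has_eardrum)) return(FALSE)
    if (!cls_pos) return(TRUE)
    !is.null(pr$box) && iou(pr$box, tr$box) > iou_threshold
  }, logical(1))
  100 * mean(correct)
}

#' Extract and resize the patch under a bounding box
#'
#' The raw crop is resized to `out_size` x `out_size` with bilinear sampling
#' (aspect distortion allowed). Boxes reaching outside the unit square are
#' clipped with a warning.
#'
#' @param frame H x W x 3 image array.
#' @param box a bounding box in normalized coordinates.
#' @param out_size output side length in pixels.
#' @return an `out_size` x `out_size` x 3 array.
#' @export
extract_patch <- function(frame, box, out_size) {
  check_image(frame, "frame")
  b <- as_box(box)
  if (b[["x_min"]] < 0 || b[["y_min"]] < 0 || b[["x_max"]] > 1 || b[["y_max"]] > 1) {
    warning("box reaches outside the frame; clipping to [0, 1]^2")
    b <- bounding_box(max(0, b[["x_min"]]), max(0, b[["y_min"]]),
                      min(1, b[["x_max"]]), min(1, b[["y_max"]]))
  }
  resize_bilinear(frame, out_size, out_size,
                  y0 = b[["y_min"]], y1 = b[["y_max"]],
                  x0 = b[["x_min"]], x1 = b[["x_max"]])
}
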