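# Ground-truth bounding boxes from phase annotations, and box IoU.
#
# Convention (used everywhere): boxes are 0-based, half-open pixel
# rectangles [x0, x1) x [y0, y1) with the origin at the image top-left;
# x is the time axis (columns), y the frequency axis (rows).
# area([x0,x1) x [y0,y1)) = (x1-x0) * (y1-y0).

#' Construct a bounding box
#'
#' @param x0,y0,x1,y1 0-based half-open pixel coordinates, `x0 < x1`,
#'   `y0 < y1`.
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1)) stop("degenerate box: need x0 < x1 and y0 < y1")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box [%g,%g) x [%g,%g)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

box_area <- function(b) max(0, b$x1 - b$x0) * max(0, b$y1 - b$y0)

#' Intersection over union of two boxes
#'
#' Half-open pixel areas; symmetric; degenerate (zero-area) boxes give 0.
#'
#' @param a,b `bounding_box` objects.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- min(a$x1, b$x1) - max(a$x0, b$x0)
  iy <- min(a$y1, b$y1) - max(a$y0, b$y0)
  inter <- max(0, ix) * max(0, iy)
  un <- box_area(a) + box_area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

# Which phases carry the diagnostic ground truth for each class: the murmur
# interval(s) for murmur classes, S1 and S2 for normal cycles.
gt_phases_for_class <- function(class_label) {
  switch(class_label,
         normal = c("S1", "S2"),
         systolic = "systole",
         diastolic = "diastole",
         abnormal = c("systole", "diastole"),
         stop("unknown class label: ", class_label))
}

#' Ground-truth boxes for a cycle's diagnostic phases
#'
#' Phase intervals are mapped through [time_to_column()]; boxes span the
#' full image height unless `band` restricts them to the pixel rows of a
#' frequency band.  Boxes are clamped, never dropped, at image borders.
#'
#' @param cycle an `annotated_cycle`.
#' @param geometry the `geometry` of the cycle's [mel_spectrogram()] image.
#' @param class_label defaults to the cycle's own label.
#' @param band optional `c(low_hz, high_hz)` frequency band restricting the
#'   vertical extent (default: full height).
#' @return object of class `gt_set`: `class_label` plus `boxes`, a named
#'   list `phase -> bounding_box`.
#' @export
phases_to_gt_boxes <- function(cycle, geometry, class_label = NULL,
                               band = NULL) {
  stopifnot(inherits(cycle, "annotated_cycle"))
  class_label <- class_label %||% cycle$class_label
  phs <- gt_phases_for_class(class_label)
  if (is.null(band)) {
    y0 <- 0; y1 <- geometry$n_rows
  } else {
    rr <- band_to_rows(band, geometry)
    y0 <- rr[1] - 1; y1 <- rr[2]
  }
  boxes <- stats::setNames(lapply(phs, function(ph) {
    iv <- cycle$phases[[ph]]
    x0 <- time_to_column(iv[1], geometry)
    x1 <- floor(iv[2] / geometry$duration_s * geometry$n_cols)
    x1 <- min(max(x1, x0 + 1), geometry$n_cols)
    bounding_box(x0, y0, x1, y1)
  }), phs)
  structure(list(class_label = class_label, boxes = boxes), class = "gt_set")
}

#' @export
print.gt_set <- function(x, ...) {
  cat(sprintf("<gt_set> class=%s, %d box(es)\n", x$class_label,
              length(x$boxes)))
  for (ph in names(x$boxes)) {
    b <- x$boxes[[ph]]
    cat(sprintf("  %-8s [%g,%g) x [%g,%g)\n", ph, b$x0, b$x1, b$y0, b$y1))
  }
  invisible(x)
}

#' Export ground-truth boxes as LabelMe-compatible rectangle JSON
#'
#' @param gt a `gt_set`.
#' @param path output JSON path.
#' @param image_path image filename recorded in the annotation.
#' @param image_size `c(height, width)` recorded in the annotation.
#' @return `path`, invisibly.
#' @export
export_labelme <- function(gt, path, image_path = "image.png",
                           image_size = c(224, 224)) {
  stopifnot(inherits(gt, "gt_set"))
  shapes <- lapply(names(gt$boxes), function(ph) {
    b <- gt$boxes[[ph]]
    list(label = ph, shape_type = "rectangle",
         points = list(c(b$x0, b$y0), c(b$x1, b$y1)),
         group_id = NULL, flags = stats::setNames(list(), character(0)))
  })
  doc <- list(version = "5.0.0",
              flags = stats::setNames(list(), character(0)),
              shapes = shapes,
              imagePath = image_path,
              imageHeight = image_size[1], imageWidth = image_size[2],
              label = gt$class_label)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a LabelMe rectangle annotation as a ground-truth box set
#'
#' Non-rectangle shapes are rejected.
#'
#' @param path LabelMe JSON file.
#' @param class_label class recorded in the set (defaults to a `label`
#'   field in the file, else `"unknown"`).
#' @return a `gt_set`.
#' @export
import_labelme <- function(path, class_label = NULL) {
  doc <- jsonlite::read_json(path)
  shapes <- doc$shapes
  if (is.null(shapes)) stop("no shapes in LabelMe file ", path)
  boxes <- list()
  for (sh in shapes) {
    if (!identical(sh$shape_type, "rectangle")) {
      stop("only rectangle shapes are supported; found shape_type='",
           sh$shape_type, "'")
    }
    p <- sh$points
    xs <- sort(c(p[[1]][[1]], p[[2]][[1]]))
    ys <- sort(c(p[[1]][[2]], p[[2]][[2]]))
    boxes[[sh$label]] <- bounding_box(xs[1], ys[1], xs[2], ys[2])
  }
  structure(list(class_label = class_label %||% doc$label %||% "unknown",
                 boxes = boxes),
            class = "gt_set")
}

#' Tabulate boxes as a data frame
#'
#' @param boxes named list of `bounding_box` (e.g. `gt_set$boxes`).
#' @param sample_id identifier recorded per row.
#' @return data.frame with columns `sample_id, phase, x0, y0, x1, y1`.
#' @export
boxes_to_table <- function(boxes, sample_id = NA) {
  if (!length(boxes)) {
    return(data.frame(sample_id = character(0), phase = character(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0)))
  }
  nm <- names(boxes) %||% as.character(seq_along(boxes))
  do.call(rbind, lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    data.frame(sample_id = sample_id, phase = nm[i], x0 = b$x0, y0 = b$y0,
               x1 = b$x1, y1 = b$y1)
  }))
}
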