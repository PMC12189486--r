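# brute-force IoU by rasterizing boxes onto a pixel grid
pixel_iou <- function(a, b, h = 224, w = 224) {
  rast <- function(bx) {
    m <- matrix(FALSE, h, w)
    xs <- seq.int(bx$x0 + 1, bx$x1)
    ys <- seq.int(bx$y0 + 1, bx$y1)
    m[ys, xs] <- TRUE
    m
  }
  ma <- rast(a); mb <- rast(b)
  inter <- sum(ma & mb); un <- sum(ma | mb)
  if (un == 0) 0 else inter / un
}

test_that("IoU matches closed-form toy cases", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_box(20, 20, 30, 30)), 0)
  expect_equal(iou(a, bounding_box(5, 0, 15, 10)), 1 / 3)
  # symmetry
  b <- bounding_box(3, 2, 12, 9)
  expect_equal(iou(a, b), iou(b, a))
  expect_error(bounding_box(5, 5, 5, 10), "degenerate")
})

test_that("IoU agrees exactly with a pixel-counting oracle on random pairs", {
  set.seed(401)
  for (i in seq_len(1000)) {
    rb <- function() {
      x <- sort(sample(0:224, 2)); y <- sort(sample(0:224, 2))
      if (x[1] == x[2]) x[2] <- x[2] + 1
      if (y[1] == y[2]) y[2] <- y[2] + 1
      bounding_box(x[1], y[1], min(x[2], 224), min(y[2], 224))
    }
    a <- rb(); b <- rb()
    expect_identical(iou(a, b), pixel_iou(a, b))
  }
})

test_that("ground-truth boxes follow the class protocol and the geometry", {
  # systole at [0.1, 0.34) of a 0.8 s cycle maps to columns [28, 95)
  p <- cycle_params("systolic",
                    phase_durations = c(S1 = 0.1, systole = 0.24,
                                        S2 = 0.06, diastole = 0.4))
  cy <- generate_cycle(p, seed = 1)
  geo <- list(n_cols = 224, n_rows = 224, duration_s = 0.8)
  gt <- phases_to_gt_boxes(cy, geo)
  expect_named(gt$boxes, "systole")
  expect_equal(gt$boxes$systole$x0, 28)
  expect_equal(gt$boxes$systole$x1, 95)
  expect_equal(gt$boxes$systole$y0, 0)
  expect_equal(gt$boxes$systole$y1, 224)

  # class protocol: which phases are annotated
  for (cl in c("normal", "systolic", "diastolic", "abnormal")) {
    pc <- cycle_params(cl)
    g <- phases_to_gt_boxes(generate_cycle(pc, 1),
                            list(n_cols = 224, n_rows = 224,
                                 duration_s = sum(pc$phase_durations)))
    expected <- switch(cl, normal = c("S1", "S2"), systolic = "systole",
                       diastolic = "diastole",
                       abnormal = c("systole", "diastole"))
    expect_named(g$boxes, expected)
  }
  expect_error(heartcam:::gt_phases_for_class("murmurish"), "unknown")
})

test_that("LabelMe export/import round-trips rectangles and rejects polygons", {
  cy <- small_cycles()[[8]]
  geo <- list(n_cols = 224, n_rows = 224,
              duration_s = length(cy$waveform) / cy$sampling_rate)
  gt <- phases_to_gt_boxes(cy, geo)
  f <- withr::local_tempfile(fileext = ".json")
  export_labelme(gt, f)
  back <- import_labelme(f)
  expect_equal(back$class_label, gt$class_label)
  expect_named(back$boxes, names(gt$boxes))
  for (ph in names(gt$boxes)) {
    expect_equal(unclass(back$boxes[[ph]]), unclass(gt$boxes[[ph]]))
  }
  # normal-class export carries two rectangle records
  cn <- generate_cycle(cycle_params("normal"), 3)
  gn <- phases_to_gt_boxes(cn, list(n_cols = 224, n_rows = 224,
                                    duration_s = sum(cycle_params("normal")$phase_durations)))
  f2 <- withr::local_tempfile(fileext = ".json")
  export_labelme(gn, f2)
  doc <- jsonlite::read_json(f2)
  expect_length(doc$shapes, 2)
  # polygon shapes are rejected
  doc$shapes[[1]]$shape_type <- "polygon"
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, null = "null")
  expect_error(import_labelme(f2), "rectangle")
})

test_that("box tables carry one row per box", {
  cy <- small_cycles()[[20]]
  geo <- list(n_cols = 224, n_rows = 224,
              duration_s = length(cy$waveform) / cy$sampling_rate)
  gt <- phases_to_gt_boxes(cy, geo)
  tab <- boxes_to_table(gt$boxes, sample_id = "s20")
  expect_equal(nrow(tab), length(gt$boxes))
  expect_equal(tab$phase, names(gt$boxes))
  expect_equal(nrow(boxes_to_table(list())), 0)
})
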