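test_that("true-positive selection is seeded, capped and shortfall-aware", {
  m <- easy_model("baseline")
  s1 <- select_true_positives(m, n_per_class = 3, seed = 4)
  s2 <- select_true_positives(m, n_per_class = 3, seed = 4)
  expect_identical(s1, s2)
  for (cl in m$classes) {
    expect_lte(length(s1$selected[[cl]]), 3)
    # selected samples are true positives from the test split
    idx <- s1$selected[[cl]]
    expect_true(all(idx %in% m$split$test))
    expect_true(all(m$labels[idx] == cl))
  }
  # asking for more than exist records the shortfall
  s3 <- select_true_positives(m, n_per_class = 50, seed = 4)
  counts <- vapply(s3$selected, length, 0L)
  expect_true(all(counts + s3$shortfall == 50))
})

test_that("sample scoring implements greedy matching with zero fill", {
  gt <- structure(list(class_label = "abnormal",
                       boxes = list(systole = bounding_box(20, 0, 90, 224),
                                    diastole = bounding_box(120, 0, 220, 224))),
                  class = "gt_set")
  # identical predictions: 1.0
  expect_equal(score_sample(unname(gt$boxes), gt)$sample_iou, 1)
  # one matching box of two: (1 + 0) / 2
  expect_equal(score_sample(list(bounding_box(20, 0, 90, 224)), gt)$sample_iou,
               0.5)
  # no predictions: 0
  expect_equal(score_sample(list(), gt)$sample_iou, 0)
  # image-sized prediction vs a GT of width fraction f: IoU = f
  gt1 <- structure(list(class_label = "systolic",
                        boxes = list(systole = bounding_box(0, 0, 56, 224))),
                   class = "gt_set")
  expect_equal(score_sample(list(bounding_box(0, 0, 224, 224)), gt1)$sample_iou,
               56 / 224)
  # greedy: a single prediction cannot be matched twice
  sc <- score_sample(list(bounding_box(20, 0, 90, 224)), gt)
  expect_equal(sum(!is.na(sc$pairs$pred_index)), 1)
})

test_that("interpretability report aggregates exactly and is reproducible", {
  m <- easy_model("baseline")
  ir <- evaluate_interpretability(m, n_per_class = 4, seed = 9)
  # aggregation identity: overall is the unweighted mean of per-class
  # values, each the mean of its per-sample rows
  per_class <- tapply(ir$per_sample$sample_iou, ir$per_sample$class, mean)
  for (cl in names(per_class)) {
    expect_equal(unname(per_class[cl]), unname(ir$per_class_miou[cl]))
  }
  expect_equal(ir$overall_miou, mean(ir$per_class_miou, na.rm = TRUE))
  expect_true(all(ir$per_sample$sample_iou >= 0 &
                    ir$per_sample$sample_iou <= 1))
  # protocol determinism
  ir2 <- evaluate_interpretability(m, n_per_class = 4, seed = 9)
  expect_identical(ir$per_sample, ir2$per_sample)
  # 4 per class x 4 classes rows when true positives suffice
  expect_lte(nrow(ir$per_sample), 16)
  expect_equal(nrow(ir$per_sample),
               sum(vapply(select_true_positives(m, 4, 9)$selected,
                          length, 0L)))
})

test_that("permutation chance level sits between 0 and the GT-width bound", {
  m <- easy_model("baseline")
  ir <- evaluate_interpretability(m, n_per_class = 3, seed = 9)
  ch <- random_box_chance(ir, n_draws = 50, seed = 10)
  expect_gte(ch$overall, 0)
  expect_lt(ch$overall, 0.6)
  # deterministic under a fixed seed
  ch2 <- random_box_chance(ir, n_draws = 50, seed = 10)
  expect_identical(ch, ch2)
})

test_that("self-comparison of identical arms yields zero differences", {
  spec <- dataset_spec(counts = c(normal = 6, systolic = 6, diastolic = 6,
                                  abnormal = 6), seed = 31)
  cmp <- suppressWarnings(
    balance_comparison(spec, spec,
                       train = train_config(max_epochs = 2, patience = 2),
                       seeds = 1, n_per_class = 2))
  expect_equal(cmp$summary$accuracy[cmp$summary$arm == "balanced"],
               cmp$summary$accuracy[cmp$summary$arm == "imbalanced"])
  expect_equal(cmp$summary$overall_miou[cmp$summary$arm == "balanced"],
               cmp$summary$overall_miou[cmp$summary$arm == "imbalanced"])
  # schema: per-run confusion matrices and per-class mIoU recorded
  expect_true(all(c("confusion", "per_class_miou") %in%
                    names(cmp$details[[1]])))
  expect_equal(dim(cmp$details[[1]]$confusion), c(4, 4))
})
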