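# Interpretability protocol: score Grad-CAM boxes against phase-derived
# ground truth on true-positive test samples; aggregate mean IoU per class
# and overall; compare balanced vs imbalanced training.

#' Select true-positive test samples per class
#'
#' A true positive is a test sample whose predicted label equals its true
#' label.  When a class has more than `n_per_class` true positives a seeded
#' uniform draw is taken; when it has fewer, all are taken and the
#' shortfall recorded.
#'
#' @param model a fitted `pcg_model`.
#' @param n_per_class samples per class (study protocol: 10).
#' @param seed selection seed.
#' @return list with `selected` (named list class -> test-set indices into
#'   the model's data) and `shortfall` (named integer vector).
#' @export
select_true_positives <- function(model, n_per_class = 10, seed = 1L) {
  idx <- model$split$test
  truth <- model$labels[idx]
  A_list <- lapply(model$features[idx], `[[`, "A")
  pred <- model$classes[max.col(predict_from_features(model, A_list))]
  selected <- list()
  shortfall <- stats::setNames(integer(length(model$classes)),
                               model$classes)
  with_seed(seed, {
    for (cl in model$classes) {
      tp <- idx[truth == cl & pred == cl]
      if (length(tp) > n_per_class) {
        tp <- sort(sample(tp, n_per_class))
      } else {
        shortfall[cl] <- n_per_class - length(tp)
      }
      selected[[cl]] <- tp
    }
  })
  list(selected = selected, shortfall = shortfall)
}

#' Score one sample's predicted boxes against its ground truth
#'
#' Greedy matching: each ground-truth box is paired with the unused
#' predicted box of highest IoU; unmatched ground-truth boxes score 0.
#' The sample IoU is the mean over ground-truth boxes (one box for the
#' single-murmur classes, the mean of two for normal/abnormal).
#'
#' @param pred_boxes list of `bounding_box` (possibly empty).
#' @param gt a `gt_set`.
#' @return list with `sample_iou` and `pairs` (data.frame of phase,
#'   matched predicted-box index or NA, and IoU).
#' @export
score_sample <- function(pred_boxes, gt) {
  stopifnot(inherits(gt, "gt_set"))
  gt_names <- names(gt$boxes)
  used <- logical(length(pred_boxes))
  rows <- list()
  for (ph in gt_names) {
    gb <- gt$boxes[[ph]]
    ious <- vapply(seq_along(pred_boxes), function(i) {
      if (used[i]) -1 else iou(pred_boxes[[i]], gb)
    }, 0)
    if (length(ious) && max(ious) >= 0) {
      j <- which.max(ious)
      used[j] <- TRUE
      rows[[ph]] <- data.frame(phase = ph, pred_index = j,
                               iou = max(ious, 0))
    } else {
      rows[[ph]] <- data.frame(phase = ph, pred_index = NA_integer_,
                               iou = 0)
    }
  }
  pairs <- do.call(rbind, rows)
  list(sample_iou = mean(pairs$iou), pairs = pairs)
}

#' Run the interpretability protocol on a fitted model
#'
#' For each selected true positive: compute the Grad-CAM map for the
#' predicted class, extract up to as many predicted boxes as the class has
#' ground-truth phases, and score them against the phase-derived boxes.
#' Per-class mean IoU is the mean over that class's samples; the overall
#' score is the unweighted mean over classes.
#'
#' Ground-truth phase boxes are time intervals (they span the image height,
#' or the rows of `band`); with `expand_rows = TRUE` (default) each
#' predicted activation box is likewise expanded to that row span before
#' scoring, so the IoU measures temporal alignment of the model's attention
#' with the annotated cardiac phase rather than the vertical extent of the
#' saliency blob.
#'
#' @param model a fitted `pcg_model`.
#' @param n_per_class true positives per class.
#' @param seed selection seed.
#' @param tau,min_area box-extraction parameters, see [heatmap_to_boxes()].
#' @param band optional frequency band restricting ground-truth box height.
#' @param expand_rows expand predicted boxes to the ground-truth row span.
#' @return object of class `iou_report`: `per_sample` (data.frame),
#'   `per_class_miou`, `overall_miou`, `shortfall`, `excluded_classes`,
#'   `box_sets` (per-sample predicted/ground-truth boxes), `params`.
#' @export
evaluate_interpretability <- function(model, n_per_class = 10, seed = 1L,
                                      tau = 0.5, min_area = 20,
                                      band = NULL, expand_rows = TRUE) {
  sel <- select_true_positives(model, n_per_class, seed)
  rows <- list()
  box_sets <- list()
  for (cl in model$classes) {
    for (i in sel$selected[[cl]]) {
      feat <- model$features[[i]]
      cam <- gradcam(model, feat$A,
                     class_index = match(cl, model$classes))
      gt <- phases_to_gt_boxes(model$data[[i]], feat$geometry,
                               class_label = cl, band = band)
      pred <- heatmap_to_boxes(cam$upsampled_map, tau = tau,
                               max_regions = length(gt$boxes),
                               min_area = min_area)
      if (expand_rows && length(pred)) {
        y0 <- gt$boxes[[1]]$y0; y1 <- gt$boxes[[1]]$y1
        pred <- lapply(pred, function(b) bounding_box(b$x0, y0, b$x1, y1))
      }
      sc <- score_sample(pred, gt)
      rows[[length(rows) + 1]] <- data.frame(sample_id = i, class = cl,
                                             sample_iou = sc$sample_iou)
      box_sets[[length(box_sets) + 1]] <- list(sample_id = i, class = cl,
                                               pred = pred, gt = gt)
    }
  }
  per_sample <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = integer(0), class = character(0),
               sample_iou = numeric(0))
  per_class <- vapply(model$classes, function(cl) {
    v <- per_sample$sample_iou[per_sample$class == cl]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  excluded <- names(per_class)[is.na(per_class)]
  if (length(excluded)) {
    warning("classes with no true positives excluded from overall mIoU: ",
            paste(excluded, collapse = ", "))
  }
  structure(list(per_sample = per_sample, per_class_miou = per_class,
                 overall_miou = mean(per_class, na.rm = TRUE),
                 shortfall = sel$shortfall, excluded_classes = excluded,
                 box_sets = box_sets,
                 params = list(n_per_class = n_per_class, seed = seed,
                               tau = tau, min_area = min_area,
                               expand_rows = expand_rows)),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("<iou_report>\n  per-class mIoU:\n")
  for (cl in names(x$per_class_miou)) {
    cat(sprintf("    %-10s %.3f\n", cl, x$per_class_miou[cl]))
  }
  cat(sprintf("  overall mIoU: %.3f (%d samples)\n", x$overall_miou,
              nrow(x$per_sample)))
  invisible(x)
}

# fast greedy sample scoring on plain coordinate matrices (columns
# x0,y0,x1,y1), used inside the permutation loop
greedy_mean_iou <- function(pred, gt) {
  if (!nrow(gt)) return(NA_real_)
  used <- logical(nrow(pred))
  tot <- 0
  for (g in seq_len(nrow(gt))) {
    best <- 0; bj <- 0
    if (nrow(pred)) {
      for (j in seq_len(nrow(pred))) {
        if (used[j]) next
        ix <- min(pred[j, 3], gt[g, 3]) - max(pred[j, 1], gt[g, 1])
        iy <- min(pred[j, 4], gt[g, 4]) - max(pred[j, 2], gt[g, 2])
        inter <- max(0, ix) * max(0, iy)
        un <- (pred[j, 3] - pred[j, 1]) * (pred[j, 4] - pred[j, 2]) +
          (gt[g, 3] - gt[g, 1]) * (gt[g, 4] - gt[g, 2]) - inter
        v <- if (un > 0) inter / un else 0
        if (v > best) { best <- v; bj <- j }
      }
    }
    if (bj > 0) used[bj] <- TRUE
    tot <- tot + best
  }
  tot / nrow(gt)
}

box_mat <- function(boxes) {
  if (!length(boxes)) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(boxes, function(b) c(b$x0, b$y0, b$x1, b$y1)))
}

#' Permutation chance level for an interpretability report
#'
#' Monte-Carlo estimate of the mean IoU expected if the model's predicted
#' activation boxes carried no temporal information: for each scored
#' sample, the predicted boxes keep their sizes but are repeatedly placed
#' uniformly at random within the image, and the sample is re-scored
#' against its ground truth.  The mean over draws and samples is the
#' chance level against which the observed mIoU is judged.
#'
#' @param report an `iou_report` from [evaluate_interpretability()].
#' @param n_draws random placements per sample.
#' @param image_size `c(rows, cols)`.
#' @param seed RNG seed.
#' @return list with `overall` (mean chance IoU), `per_class` (named
#'   vector), and `n_draws`.
#' @export
random_box_chance <- function(report, n_draws = 1000,
                              image_size = c(224, 224), seed = 1L) {
  stopifnot(inherits(report, "iou_report"))
  h <- image_size[1]; w <- image_size[2]
  per_sample <- numeric(length(report$box_sets))
  cls <- character(length(report$box_sets))
  with_seed(seed, {
    for (k in seq_along(report$box_sets)) {
      bs <- report$box_sets[[k]]
      cls[k] <- bs$class
      gt <- box_mat(bs$gt$boxes)
      pred <- box_mat(bs$pred)
      if (!nrow(pred)) { per_sample[k] <- 0; next }
      acc <- 0
      for (d in seq_len(n_draws)) {
        rp <- pred
        for (j in seq_len(nrow(pred))) {
          bw <- pred[j, 3] - pred[j, 1]; bh <- pred[j, 4] - pred[j, 2]
          x0 <- floor(stats::runif(1, 0, max(w - bw, 0) + 1))
          y0 <- floor(stats::runif(1, 0, max(h - bh, 0) + 1))
          rp[j, ] <- c(x0, y0, x0 + bw, y0 + bh)
        }
        acc <- acc + greedy_mean_iou(rp, gt)
      }
      per_sample[k] <- acc / n_draws
    }
  })
  per_class <- tapply(per_sample, cls, mean)
  list(overall = mean(per_sample), per_class = per_class,
       n_draws = n_draws)
}

#' Balanced-versus-imbalanced training comparison
#'
#' Trains the same backbone/head on a balanced and an imbalanced dataset
#' specification, for each seed, and reports accuracy and overall mIoU per
#' arm together with their differences.
#'
#' @param balanced,imbalanced [dataset_spec()]s for the two arms.
#' @param backbone a [backbone_spec()].
#' @param head a [head_config()].
#' @param train a [train_config()] (its seed is replaced per replicate).
#' @param seeds integer vector of replicate seeds.
#' @param n_per_class true positives per class for the IoU protocol.
#' @param tau box-extraction threshold.
#' @return object of class `balance_comparison`: `replicates` (data.frame
#'   with one row per seed and arm), `summary` (mean per arm), and
#'   `details` (per-run confusion matrices and per-class mIoU).
#' @export
balance_comparison <- function(balanced, imbalanced,
                               backbone = backbone_spec("tiny_test"),
                               head = head_config("baseline"),
                               train = train_config(),
                               seeds = 1:3, n_per_class = 10, tau = 0.5) {
  rows <- list(); details <- list()
  for (arm in c("balanced", "imbalanced")) {
    spec0 <- if (arm == "balanced") balanced else imbalanced
    for (s in seeds) {
      spec <- spec0
      spec$seed <- derive_seed(s, "data")
      cycles <- generate_dataset(spec)
      tc <- train
      tc$seed <- derive_seed(s, "train")
      model <- fit_pcg_classifier(cycles, backbone = backbone, head = head,
                                  train = tc)
      ev <- evaluate_model(model)
      ir <- evaluate_interpretability(model, n_per_class = n_per_class,
                                      seed = derive_seed(s, "select"),
                                      tau = tau)
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, seed = s, accuracy = ev$accuracy,
        overall_miou = ir$overall_miou)
      details[[paste(arm, s, sep = "_")]] <-
        list(confusion = ev$confusion, per_class_miou = ir$per_class_miou)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$arm), function(d) {
    data.frame(arm = d$arm[1], accuracy = mean(d$accuracy),
               overall_miou = mean(d$overall_miou))
  }))
  structure(list(replicates = reps, summary = summ, details = details),
            class = "balance_comparison")
}

#' @export
print.balance_comparison <- function(x, ...) {
  cat("<balance_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
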