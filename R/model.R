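# Classifier heads on a frozen backbone: configuration, fitting,
# prediction and evaluation.
#
# Three head variants sit on the backbone's last convolutional feature map:
#   baseline: GAP -> 3 x (dense + ReLU + dropout) -> softmax(4)
#   se:       SE block -> GAP -> same dense tail as baseline
#   mha:      multi-head self-attention -> Gaussian noise (train only) ->
#             GAP -> 3 x (dense + batch norm + ReLU) -> softmax(4)
# The backbone is frozen: its parameters receive no updates; training
# operates on cached backbone features.

#' Classifier head configuration
#'
#' Defaults follow the study setup: an eight-head attention block with key
#' dimension 128 for the `mha` variant, squeeze-and-excitation reduction
#' ratio 16 for `se`, and a 256/128/64 dense tail with dropout 0.3.
#'
#' @param variant `"baseline"`, `"se"` or `"mha"`.
#' @param se_ratio SE bottleneck reduction ratio r.
#' @param mha_heads number of attention heads h.
#' @param mha_key_dim per-head key/query dimension d_k.
#' @param mha_value_dim per-head value dimension d_v (defaults to d_k).
#' @param dense_sizes hidden dense-layer widths.
#' @param dropout_rate dropout after each hidden dense layer
#'   (baseline/se variants).
#' @param gaussian_noise_std train-time additive noise after the attention
#'   block (mha variant).
#' @param n_classes number of output classes.
#' @return object of class `head_config`.
#' @export
head_config <- function(variant = c("baseline", "se", "mha"),
                        se_ratio = 16, mha_heads = 8, mha_key_dim = 128,
                        mha_value_dim = mha_key_dim,
                        dense_sizes = c(256, 128, 64), dropout_rate = 0.1,
                        gaussian_noise_std = 0.1, n_classes = 4) {
  variant <- match.arg(variant)
  structure(list(variant = variant, se_ratio = se_ratio,
                 mha_heads = mha_heads, mha_key_dim = mha_key_dim,
                 mha_value_dim = mha_value_dim, dense_sizes = dense_sizes,
                 dropout_rate = dropout_rate,
                 gaussian_noise_std = gaussian_noise_std,
                 n_classes = n_classes),
            class = "head_config")
}

#' Training configuration
#'
#' Defaults: 70/15/15 stratified split, batch size 5, Adam with learning
#' rate 1e-4, early stopping on validation categorical accuracy with
#' patience 10 and best-weight restoration.
#'
#' @param split numeric length-3 train/validation/test fractions
#'   (must sum to 1).
#' @param batch_size samples per gradient step.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   accuracy improvement).
#' @param max_epochs epoch cap.
#' @param seed seed controlling the split, initialization and train-time
#'   randomness.
#' @return object of class `train_config`.
#' @export
train_config <- function(split = c(0.70, 0.15, 0.15), batch_size = 5,
                         learning_rate = 1e-4, patience = 10,
                         max_epochs = 100, seed = 1L) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-9)
  structure(list(split = split, batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience,
                 max_epochs = max_epochs, seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' @param labels character or factor vector of class labels.
#' @param split length-3 fractions summing to 1.
#' @param seed permutation seed.
#' @return list of integer index vectors `train`, `val`, `test`
#'   (disjoint, covering all samples, stratified by class).
#' @export
stratified_split <- function(labels, split = c(0.70, 0.15, 0.15), seed = 1L) {
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in unique(labels)) {
      pool <- sample(which(labels == cl))
      n <- length(pool)
      n_tr <- round(split[1] * n)
      n_va <- round(split[2] * n)
      # guarantee each split at least one sample per class when n allows
      if (n >= 3) {
        n_tr <- max(1, min(n_tr, n - 2))
        n_va <- max(1, min(n_va, n - n_tr - 1))
      } else if (n_tr + n_va >= n) {
        n_va <- max(0, n - n_tr - 1)
      }
      idx$train <- c(idx$train, pool[seq_len(n_tr)])
      idx$val <- c(idx$val, pool[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, pool[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
  })
  idx
}

# ---- head parameter construction -------------------------------------------

head_init <- function(head, channels, seed) {
  params <- list()
  use_bn <- head$variant == "mha"
  if (head$variant == "se") {
    params$se <- se_params(channels, head$se_ratio,
                           seed = derive_seed(seed, "se"))
  }
  if (head$variant == "mha") {
    params$mha <- mha_params(channels, head$mha_heads, head$mha_key_dim,
                             head$mha_value_dim,
                             seed = derive_seed(seed, "mha"))
  }
  params$tail <- dense_init(head$dense_sizes, channels, head$n_classes,
                            use_bn, seed = derive_seed(seed, "tail"))
  params
}

head_bn_states <- function(head) {
  if (head$variant != "mha") return(NULL)
  lapply(head$dense_sizes, function(sz) list(mean = numeric(sz),
                                             var = rep(1, sz)))
}

# Forward over a list of feature maps.  Returns logits plus caches needed
# for the backward pass.  Train-time stochastic layers (dropout, Gaussian
# noise) draw from the current RNG stream.
head_forward <- function(params, head, A_list, training, bn_states) {
  use_bn <- head$variant == "mha"
  spatial_caches <- vector("list", length(A_list))
  G <- matrix(0, length(A_list),
              dim(A_list[[1]])[3])
  noise_masks <- vector("list", length(A_list))
  for (b in seq_along(A_list)) {
    A <- A_list[[b]]
    sc <- NULL
    if (head$variant == "baseline") {
      Z <- A
    } else if (head$variant == "se") {
      fw <- se_forward(A, params$se)
      Z <- fw$out; sc <- fw$cache
    } else {
      fw <- mha_forward(A, params$mha)
      Z <- fw$out; sc <- fw$cache
      if (training && head$gaussian_noise_std > 0) {
        eps <- array(stats::rnorm(length(Z), sd = head$gaussian_noise_std),
                     dim = dim(Z))
        Z <- Z + eps
      }
    }
    G[b, ] <- colMeans(matrix(Z, ncol = dim(Z)[3]))
    spatial_caches[[b]] <- list(cache = sc, dims = dim(A))
  }
  tf <- tail_forward(G, params$tail, bn_states, training,
                     head$dropout_rate, use_bn)
  list(logits = tf$logits, tail_caches = tf$caches,
       bn_states = tf$bn_states, spatial_caches = spatial_caches, G = G)
}

# Backward from dLogits to parameter gradients (and optionally input-map
# gradients).  Returns summed gradients over the batch.
head_backward <- function(params, head, fw, dLogits, want_dA = FALSE) {
  use_bn <- head$variant == "mha"
  tb <- tail_backward(dLogits, params$tail, fw$tail_caches, use_bn)
  grads <- list(tail = tb$grads)
  dA_list <- if (want_dA) vector("list", length(fw$spatial_caches)) else NULL
  for (b in seq_along(fw$spatial_caches)) {
    sc <- fw$spatial_caches[[b]]
    d <- sc$dims
    hw <- d[1] * d[2]
    # GAP backward: gradient of channel mean spread uniformly over space
    dZ <- array(rep(tb$dG[b, ], each = hw) / hw, dim = d)
    if (head$variant == "baseline") {
      dA <- dZ
    } else if (head$variant == "se") {
      bw <- se_backward(dZ, sc$cache, params$se)
      grads$se <- grads_add(grads$se %||% NULL, bw$grads)
      dA <- bw$dA
    } else {
      bw <- mha_backward(dZ, sc$cache, params$mha)
      grads$mha <- grads_add(grads$mha %||% NULL, bw$grads)
      dA <- bw$dA
    }
    if (want_dA) dA_list[[b]] <- dA
  }
  list(grads = grads, dA_list = dA_list)
}

#' Count trainable head parameters
#'
#' @param model a `pcg_model` (fitted or built).
#' @return integer number of trainable scalars in the head.
#' @export
n_head_params <- function(model) {
  count <- function(x) if (is.list(x)) sum(vapply(x, count, 0)) else length(x)
  count(model$params)
}

# ---- model object -----------------------------------------------------------

#' Build an (untrained) classifier on a frozen backbone
#'
#' @param backbone a [backbone_spec()].
#' @param head a [head_config()].
#' @param preprocess a [preprocess_config()].
#' @param seed initialization seed.
#' @return object of class `pcg_model` with `fitted = FALSE`.
#' @export
build_pcg_model <- function(backbone = backbone_spec("tiny_test"),
                            head = head_config("baseline"),
                            preprocess = preprocess_config(),
                            seed = 1L) {
  bb <- backbone_build(backbone)
  params <- head_init(head, bb$out_channels, seed)
  structure(list(backbone = bb, head = head, preprocess = preprocess,
                 params = params, bn_states = head_bn_states(head),
                 classes = PCG_CLASSES, fitted = FALSE,
                 init_seed = as.integer(seed)),
            class = "pcg_model")
}

# preprocess + frozen backbone features for a list of cycles.  When the
# model carries feature-normalization statistics (frozen per-channel
# standardization closing the backbone, computed once from the training
# split), they are applied here, so the normalized map is the backbone's
# final output everywhere (training, prediction, Grad-CAM target).
compute_features <- function(model, cycles, verbose = FALSE) {
  lapply(seq_along(cycles), function(i) {
    cy <- cycles[[i]]
    wf <- butterworth_lowpass(cy$waveform, cy$sampling_rate,
                              model$preprocess)
    img <- mel_spectrogram(wf, cy$sampling_rate, model$preprocess)
    A <- backbone_forward(model$backbone, img$pixels)
    if (!is.null(model$feat_norm)) A <- normalize_feature_map(A, model$feat_norm)
    list(A = A, geometry = img$geometry)
  })
}

normalize_feature_map <- function(A, fn) {
  d <- dim(A)
  X <- sweep(sweep(matrix(A, ncol = d[3]), 2, fn$mean), 2, fn$sd, "/")
  array(X, dim = d)
}

# per-channel mean/sd over a list of feature maps
feature_norm_stats <- function(A_list) {
  C <- dim(A_list[[1]])[3]
  X <- do.call(rbind, lapply(A_list, function(A) matrix(A, ncol = C)))
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  list(mean = mu, sd = pmax(sd, 1e-6))
}

#' Fit a heart-sound classifier head on a frozen backbone
#'
#' Cycles are low-pass filtered, converted to mel-spectrogram images and
#' passed through the frozen backbone once; the head is then trained on the
#' cached feature maps with Adam and softmax cross-entropy.  Early stopping
#' monitors validation categorical accuracy (patience per `train$patience`)
#' and the best-epoch weights are restored.
#'
#' @param cycles list of `annotated_cycle` objects.
#' @param backbone a [backbone_spec()].
#' @param head a [head_config()].
#' @param preprocess a [preprocess_config()].
#' @param train a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a fitted `pcg_model`; fields include `history` (per-epoch data
#'   frame), `split` (index vectors), `features` (cached test-split feature
#'   maps and geometries), and `data` (the input cycles).
#' @export
fit_pcg_classifier <- function(cycles,
                               backbone = backbone_spec("tiny_test"),
                               head = head_config("baseline"),
                               preprocess = preprocess_config(),
                               train = train_config(),
                               verbose = FALSE) {
  stopifnot(length(cycles) > 0)
  model <- build_pcg_model(backbone, head, preprocess,
                           seed = derive_seed(train$seed, "init"))
  labels <- vapply(cycles, function(c) c$class_label, "")
  y <- match(labels, model$classes)
  if (anyNA(y)) stop("unknown class label in cycles")
  split <- stratified_split(labels, train$split,
                            seed = derive_seed(train$seed, "split"))
  if (!length(split$train) || !length(split$val)) {
    stop("empty training or validation split")
  }
  feats <- compute_features(model, cycles)
  model$feat_norm <- feature_norm_stats(lapply(feats[split$train], `[[`, "A"))
  feats <- lapply(feats, function(f) {
    f$A <- normalize_feature_map(f$A, model$feat_norm)
    f
  })
  A_all <- lapply(feats, `[[`, "A")

  params <- model$params
  bn_states <- model$bn_states
  opt <- adam_init(params)
  best <- list(acc = -Inf, epoch = 0L, params = params,
               bn_states = bn_states)
  history <- data.frame()
  tr <- split$train
  with_seed(derive_seed(train$seed, "train"), {
    for (epoch in seq_len(train$max_epochs)) {
      order_tr <- sample(tr)
      ep_loss <- 0; ep_correct <- 0
      for (s in seq(1, length(order_tr), by = train$batch_size)) {
        bidx <- order_tr[s:min(s + train$batch_size - 1, length(order_tr))]
        fw <- head_forward(params, head, A_all[bidx], training = TRUE,
                           bn_states)
        bn_states <- fw$bn_states
        sx <- softmax_xent(fw$logits, y[bidx])
        bw <- head_backward(params, head, fw, sx$dLogits)
        step <- adam_step(params, bw$grads, opt, lr = train$learning_rate)
        params <- step$params
        opt <- step$state
        ep_loss <- ep_loss + sx$loss * length(bidx)
        ep_correct <- ep_correct + sum(max.col(sx$probs) == y[bidx])
      }
      # validation (eval mode)
      va <- split$val
      fw_v <- head_forward(params, head, A_all[va], training = FALSE,
                           bn_states)
      sx_v <- softmax_xent(fw_v$logits, y[va])
      val_acc <- mean(max.col(sx_v$probs) == y[va])
      history <- rbind(history, data.frame(
        epoch = epoch,
        train_loss = ep_loss / length(tr),
        train_acc = ep_correct / length(tr),
        val_loss = sx_v$loss, val_acc = val_acc))
      if (!is.finite(sx_v$loss)) stop("non-finite validation loss at epoch ",
                                      epoch)
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, epoch = epoch, params = params,
                     bn_states = bn_states)
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %.3f",
                        epoch, ep_loss / length(tr),
                        ep_correct / length(tr), val_acc))
      }
      if (epoch - best$epoch >= train$patience) break
    }
  })
  model$params <- best$params
  model$bn_states <- best$bn_states
  model$best_epoch <- best$epoch
  model$history <- history
  model$split <- split
  model$train_config <- train
  model$labels <- labels
  model$y <- y
  model$features <- feats
  model$data <- cycles
  model$fitted <- TRUE
  model
}

# predict probabilities from cached feature maps
predict_from_features <- function(model, A_list) {
  fw <- head_forward(model$params, model$head, A_list, training = FALSE,
                     model$bn_states)
  probs <- softmax_rows(fw$logits)
  colnames(probs) <- model$classes
  probs
}

#' Predict classes or probabilities for heartbeat cycles
#'
#' @param object a fitted `pcg_model`.
#' @param newdata list of `annotated_cycle`s; defaults to the model's own
#'   test split.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character vector of class labels, or a probability matrix with
#'   one row per cycle.
#' @export
predict.pcg_model <- function(object, newdata = NULL,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!object$fitted) stop("model is not fitted")
  if (is.null(newdata)) {
    A_list <- lapply(object$features[object$split$test], `[[`, "A")
  } else {
    A_list <- lapply(compute_features(object, newdata), `[[`, "A")
  }
  probs <- predict_from_features(object, A_list)
  if (type == "prob") probs else object$classes[max.col(probs)]
}

#' @export
print.pcg_model <- function(x, ...) {
  cat(sprintf("<pcg_model> %s head on frozen %s backbone (%s)\n",
              x$head$variant, x$backbone$spec$name,
              if (x$fitted) "fitted" else "untrained"))
  cat(sprintf("  head parameters: %d\n", n_head_params(x)))
  if (x$fitted) {
    cat(sprintf("  trained %d epochs (best epoch %d, val acc %.3f)\n",
                nrow(x$history), x$best_epoch,
                max(x$history$val_acc)))
  }
  invisible(x)
}

#' @export
summary.pcg_model <- function(object, ...) {
  print(object)
  if (object$fitted) {
    ev <- evaluate_model(object)
    cat(sprintf("  test accuracy: %.3f  macro F1: %.3f\n",
                ev$accuracy, ev$macro_f1))
    cat("  confusion matrix (rows = truth):\n")
    print(ev$confusion)
    invisible(ev)
  } else {
    invisible(object)
  }
}

#' Plot training curves
#'
#' @param x a fitted `pcg_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pcg_model <- function(x, ...) {
  if (!x$fitted) stop("model is not fitted")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "categorical accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("train", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

# ---- evaluation -------------------------------------------------------------

#' Classification metrics on a labelled set
#'
#' Accuracy is the fraction of correct predictions (the trace of the
#' confusion matrix over its total); per-class precision, recall and F1 are
#' computed one-vs-rest.  A class absent from the evaluation set gets `NA`
#' (not zero) F1 and is flagged.
#'
#' @param model a fitted `pcg_model`.
#' @param cycles evaluation cycles; defaults to the model's test split.
#' @param labels true labels (defaults to the cycles' own labels).
#' @return list with `accuracy`, `per_class` (data.frame of precision /
#'   recall / F1 / support), `macro_f1`, `confusion` (4x4 matrix, rows =
#'   truth), `n`, and `absent_classes`.
#' @export
evaluate_model <- function(model, cycles = NULL, labels = NULL) {
  if (is.null(cycles)) {
    idx <- model$split$test
    if (!length(idx)) stop("model has no test split")
    A_list <- lapply(model$features[idx], `[[`, "A")
    truth <- model$labels[idx]
  } else {
    A_list <- lapply(compute_features(model, cycles), `[[`, "A")
    truth <- labels %||% vapply(cycles, function(c) c$class_label, "")
  }
  probs <- predict_from_features(model, A_list)
  pred <- model$classes[max.col(probs)]
  classes <- model$classes
  conf <- table(factor(truth, classes), factor(pred, classes))
  conf <- matrix(conf, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  per <- lapply(seq_along(classes), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    support <- sum(conf[k, ])
    if (support == 0) {
      return(data.frame(class = classes[k], precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_, support = 0))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = classes[k], precision = prec, recall = rec, f1 = f1,
               support = support)
  })
  per <- do.call(rbind, per)
  absent <- per$class[per$support == 0]
  list(accuracy = acc, per_class = per,
       macro_f1 = mean(per$f1, na.rm = TRUE), confusion = conf, n = n,
       absent_classes = as.character(absent))
}

#' Binary one-vs-rest accuracy from counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return accuracy in `[0, 1]`.
#' @export
binary_accuracy <- function(tp, tn, fp, fn) (tp + tn) / (tp + tn + fp + fn)

#' F1 score from counts
#'
#' Harmonic mean of precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#'
#' @param tp,fp,fn confusion counts.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
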