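# Grad-CAM localization maps and predicted-box extraction.
#
# For a class score y^c (pre-softmax logit by default), the neuron
# importance weight of feature-map channel k is the spatial mean of
# dy^c/dA^k; the localization map is ReLU of the weighted channel sum,
# upsampled bilinearly to the input image size and max-normalized.

#' Compute a Grad-CAM localization map
#'
#' The target layer is the frozen backbone's last convolutional output
#' (the feature map the head consumes); gradients of the class score with
#' respect to it are obtained by backpropagation through the head in
#' evaluation mode.
#'
#' @param model a fitted `pcg_model`.
#' @param input an `annotated_cycle`, a `mel_image`, or a feature-map array
#'   as produced by the backbone.
#' @param class_index 1-based class index (or class name); defaults to the
#'   model's predicted class.
#' @param score `"logit"` (default, standard Grad-CAM practice) or
#'   `"prob"` to differentiate the post-softmax score.
#' @param out_size size of the upsampled map (defaults to the preprocess
#'   output size).
#' @return object of class `gradcam_result`: `feature_map` (A), `gradients`
#'   (dy^c/dA), `weights` (alpha_k, one per channel), `map` (ReLU-ed H'xW'
#'   localization map), `upsampled_map` (out_size, max-normalized to [0,1];
#'   all-zero maps stay all-zero), `class_index`, `class_label`, `probs`.
#' @export
gradcam <- function(model, input, class_index = NULL,
                    score = c("logit", "prob"), out_size = NULL) {
  score <- match.arg(score)
  if (!model$fitted) stop("model is not fitted")
  out_size <- out_size %||% model$preprocess$out_size
  A <- gradcam_input_features(model, input)
  fw <- head_forward(model$params, model$head, list(A), training = FALSE,
                     model$bn_states)
  probs <- softmax_rows(fw$logits)
  if (is.null(class_index)) {
    class_index <- which.max(probs[1, ])
  } else if (is.character(class_index)) {
    class_index <- match(class_index, model$classes)
    if (is.na(class_index)) stop("unknown class name")
  }
  dLogits <- matrix(0, 1, model$head$n_classes)
  if (score == "logit") {
    dLogits[1, class_index] <- 1
  } else {
    # d p_c / d logits = p_c * (1[j=c] - p_j)
    p <- probs[1, ]
    dLogits[1, ] <- p[class_index] * ((seq_along(p) == class_index) - p)
  }
  bw <- head_backward(model$params, model$head, fw, dLogits, want_dA = TRUE)
  dA <- bw$dA_list[[1]]
  if (!is.null(model$feat_norm)) {
    # the Grad-CAM target is the backbone's raw convolutional output; the
    # frozen standardization belongs to the head input path, so invert it
    # on the activations and chain it through the gradients
    d <- dim(A)
    A <- array(sweep(sweep(matrix(A, ncol = d[3]), 2, model$feat_norm$sd,
                           "*"),
                     2, model$feat_norm$mean, "+"), d)
    dA <- array(sweep(matrix(dA, ncol = d[3]), 2, model$feat_norm$sd, "/"),
                d)
  }
  gradcam_from_gradients(A, dA, out_size = out_size,
                         class_index = class_index,
                         class_label = model$classes[class_index],
                         probs = probs[1, , drop = TRUE])
}

gradcam_input_features <- function(model, input) {
  if (is.array(input) && length(dim(input)) == 3 && !inherits(input, "mel_image")) {
    return(input)
  }
  if (inherits(input, "annotated_cycle")) {
    wf <- butterworth_lowpass(input$waveform, input$sampling_rate,
                              model$preprocess)
    input <- mel_spectrogram(wf, input$sampling_rate, model$preprocess)
  }
  if (inherits(input, "mel_image")) {
    A <- backbone_forward(model$backbone, input$pixels)
    if (!is.null(model$feat_norm)) A <- normalize_feature_map(A, model$feat_norm)
    return(A)
  }
  stop("unsupported input type for gradcam()")
}

#' Assemble a Grad-CAM result from a feature map and its gradients
#'
#' The core arithmetic, exposed separately so it can be driven by any
#' source of gradients: `alpha_k = mean_ij dy/dA_k[i,j]`,
#' `L = ReLU(sum_k alpha_k A_k)`, bilinear upsampling, max-normalization.
#'
#' @param A feature map `H' x W' x K`.
#' @param dA gradient array of the same shape.
#' @param out_size `c(rows, cols)` for the upsampled map.
#' @param class_index,class_label,probs metadata carried through.
#' @return a `gradcam_result` (see [gradcam()]).
#' @export
gradcam_from_gradients <- function(A, dA, out_size = c(224, 224),
                                   class_index = NA, class_label = NA,
                                   probs = NULL) {
  stopifnot(identical(dim(A), dim(dA)))
  K <- dim(A)[3]
  alpha <- vapply(seq_len(K), function(k) mean(dA[, , k]), 0)
  L <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) L <- L + alpha[k] * A[, , k]
  L <- pmax(L, 0)
  up <- resize_bilinear(L, out_size[1], out_size[2])
  up <- pmax(up, 0)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(feature_map = A, gradients = dA, weights = alpha,
                 map = L, upsampled_map = up, class_index = class_index,
                 class_label = class_label, probs = probs),
            class = "gradcam_result")
}

#' @export
print.gradcam_result <- function(x, ...) {
  cat(sprintf("<gradcam_result> class=%s, map %dx%d -> %dx%d, max weight %.3g\n",
              as.character(x$class_label), nrow(x$map), ncol(x$map),
              nrow(x$upsampled_map), ncol(x$upsampled_map),
              max(abs(x$weights))))
  invisible(x)
}

#' Extract predicted activation boxes from a saliency map
#'
#' The map is binarized at `tau * max(map)`; 8-connected components smaller
#' than `min_area` pixels are discarded; the remaining components are
#' ranked by total activation mass (ties broken by `x0`, then `y0`) and the
#' top `max_regions` are returned as tight bounding boxes.
#'
#' @param map numeric matrix in `[0, 1]` (e.g. `upsampled_map` of a
#'   [gradcam()] result).
#' @param tau threshold fraction of the map maximum, in (0, 1).
#' @param max_regions maximum number of boxes returned.
#' @param min_area minimum component area in pixels.
#' @return list of `bounding_box` (possibly empty, e.g. for an all-zero
#'   map).
#' @export
heatmap_to_boxes <- function(map, tau = 0.5, max_regions = 2,
                             min_area = 20) {
  stopifnot(is.matrix(map), tau > 0, tau < 1)
  mx <- max(map)
  if (mx <= 0) return(list())
  mask <- map >= tau * mx
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0) return(list())
  comps <- lapply(seq_len(k), function(id) {
    sel <- which(lab == id, arr.ind = TRUE)
    area <- nrow(sel)
    mass <- sum(map[lab == id])
    # R indices are 1-based; boxes are 0-based half-open
    x0 <- min(sel[, 2]) - 1; x1 <- max(sel[, 2])
    y0 <- min(sel[, 1]) - 1; y1 <- max(sel[, 1])
    list(area = area, mass = mass, box = bounding_box(x0, y0, x1, y1))
  })
  comps <- Filter(function(cp) cp$area >= min_area, comps)
  if (!length(comps)) return(list())
  ord <- order(-vapply(comps, `[[`, 0, "mass"),
               vapply(comps, function(cp) cp$box$x0, 0),
               vapply(comps, function(cp) cp$box$y0, 0))
  comps <- comps[ord]
  lapply(utils::head(comps, max_regions), `[[`, "box")
}

#' Write a Grad-CAM overlay image
#'
#' Renders the mel image in grayscale, blends the saliency map in red, and
#' draws ground-truth (green) and predicted (black) box outlines, mirroring
#' the usual published overlay style.
#'
#' @param image a `mel_image`.
#' @param cam a `gradcam_result`.
#' @param gt_boxes,pred_boxes lists of `bounding_box` (possibly empty).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, cam, gt_boxes = list(),
                              pred_boxes = list(), path) {
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  heat <- cam$upsampled_map
  rgb <- array(0, dim = c(h, w, 3))
  base <- 0.7 * px
  rgb[, , 1] <- clamp(base + 0.6 * heat, 0, 1)
  rgb[, , 2] <- base
  rgb[, , 3] <- base
  draw_box <- function(rgb, b, col) {
    # 0-based half-open -> 1-based inclusive pixel edges
    r0 <- clamp(b$y0 + 1, 1, h); r1 <- clamp(b$y1, 1, h)
    c0 <- clamp(b$x0 + 1, 1, w); c1 <- clamp(b$x1, 1, w)
    for (ch in 1:3) {
      rgb[r0:r1, c(c0, c1), ch] <- col[ch]
      rgb[c(r0, r1), c0:c1, ch] <- col[ch]
    }
    rgb
  }
  for (b in gt_boxes) rgb <- draw_box(rgb, b, c(0, 0.8, 0))
  for (b in pred_boxes) rgb <- draw_box(rgb, b, c(0, 0, 0))
  png::writePNG(rgb, path)
  invisible(path)
}
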