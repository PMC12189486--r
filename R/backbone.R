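# Frozen convolutional backbones.
#
# The package's experiments run on `tiny_test`: a small, randomly
# initialized, frozen convolutional feature extractor (2x2 average-pool
# stem, then three stride-2 3x3 conv + ReLU blocks ending at 32 channels),
# giving a 14x14x32 feature map for a 224x224x3 input.  The named
# large-scale architectures of the transfer-learning literature are
# registered for completeness but require pretrained weights that this
# package does not ship.

BACKBONE_NAMES <- c("tiny_test", "resnet50", "resnet152", "mobilenet",
                    "mobilenetv2", "vgg19", "efficientnetv2b0")

#' Describe a backbone
#'
#' @param name one of `tiny_test`, `resnet50`, `resnet152`, `mobilenet`,
#'   `mobilenetv2`, `vgg19`, `efficientnetv2b0`.  Only `tiny_test` can be
#'   instantiated without user-supplied pretrained weights.
#' @param pretrained logical; pretrained weights are never bundled, so this
#'   must be `FALSE` for `tiny_test`.
#' @param seed seed for the (frozen) random initialization of `tiny_test`.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "tiny_test", pretrained = FALSE, seed = 42L) {
  name <- match.arg(name, BACKBONE_NAMES)
  structure(list(name = name, pretrained = pretrained,
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

tiny_test_channels <- c(16, 24, 32)

# instantiate frozen weights for a backbone spec
backbone_build <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$name != "tiny_test") {
    stop("backbone '", spec$name, "' requires pretrained weights, which are ",
         "not bundled with this package; use backbone_spec('tiny_test') ",
         "or supply your own feature extractor")
  }
  chans <- tiny_test_channels
  c_in <- c(3, chans[-length(chans)])
  with_seed(spec$seed, {
    convs <- lapply(seq_along(chans), function(i) {
      fan_in <- 9 * c_in[i]
      list(W = matrix(stats::rnorm(fan_in * chans[i],
                                   sd = sqrt(2 / fan_in)),
                      fan_in, chans[i]),
           b = numeric(chans[i]),
           c_in = c_in[i], c_out = chans[i])
    })
    list(spec = spec, convs = convs, out_channels = chans[length(chans)])
  })
}

# 2x2 average pooling (stride 2) of an H x W x C array
avg_pool2 <- function(A) {
  d <- dim(A)
  h <- d[1] %/% 2; w <- d[2] %/% 2
  i1 <- seq(1, 2 * h, by = 2); j1 <- seq(1, 2 * w, by = 2)
  (A[i1, j1, , drop = FALSE] + A[i1 + 1, j1, , drop = FALSE] +
     A[i1, j1 + 1, , drop = FALSE] + A[i1 + 1, j1 + 1, , drop = FALSE]) / 4
}

# stride-2, pad-1, 3x3 convolution via im2col.  W is (9*C_in) x C_out with
# column-major patch flattening (row offset fastest, then col offset, then
# input channel) matching array(, c(3,3,C_in)) flattening.
conv3x3_s2 <- function(A, W, b) {
  d <- dim(A)
  h <- d[1]; w <- d[2]; cin <- d[3]
  oh <- (h - 1) %/% 2 + 1; ow <- (w - 1) %/% 2 + 1
  P <- array(0, dim = c(h + 2, w + 2, cin))
  P[2:(h + 1), 2:(w + 1), ] <- A
  ri <- 2 * (seq_len(oh) - 1) + 1 # top-left row of each patch in padded P
  rj <- 2 * (seq_len(ow) - 1) + 1
  cols <- matrix(0, oh * ow, 9 * cin)
  col <- 0L
  for (cc in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        cols[, col] <- as.vector(P[ri + di, rj + dj, cc])
      }
    }
  }
  out <- sweep(cols %*% W, 2, b, "+")
  array(out, dim = c(oh, ow, ncol(W)))
}

# forward pass of the frozen tiny_test backbone; input is a 224x224 matrix
# in [0,1] (replicated to 3 channels at this boundary) or an H x W x 3 array
backbone_forward <- function(bb, img) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  A <- avg_pool2(img)
  for (cv in bb$convs) {
    A <- relu(conv3x3_s2(A, cv$W, cv$b))
  }
  A
}
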