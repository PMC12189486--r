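test_that("Grad-CAM reproduces the hand-computed toy case exactly", {
  # one 2x2 feature map A = [[1,2],[3,4]], score y = A[1,1] + A[2,2]:
  # gradient is the identity pattern, alpha = 1/4 * (1 + 1) = 0.5,
  # L = ReLU(0.5 * A)
  A <- array(matrix(c(1, 3, 2, 4), 2, 2), dim = c(2, 2, 1))
  dA <- array(diag(2), dim = c(2, 2, 1))
  res <- gradcam_from_gradients(A, dA, out_size = c(2, 2))
  expect_equal(res$weights, 0.5)
  expect_equal(res$map, matrix(c(0.5, 1.5, 1, 2), 2, 2))
  expect_true(all(res$map >= 0))
  expect_equal(max(res$upsampled_map), 1)
})

test_that("Grad-CAM maps are nonnegative and zero maps stay zero", {
  set.seed(12)
  A <- array(rnorm(32), dim = c(4, 4, 2))
  dA <- array(rnorm(32), dim = c(4, 4, 2))
  res <- gradcam_from_gradients(A, dA)
  expect_gte(min(res$map), 0)
  expect_gte(min(res$upsampled_map), 0)
  expect_lte(max(res$upsampled_map), 1)
  # identically negative weighted sum -> all-zero map stays all-zero
  z <- gradcam_from_gradients(array(1, c(2, 2, 1)), array(-1, c(2, 2, 1)))
  expect_true(all(z$upsampled_map == 0))
})

test_that("Grad-CAM is linear in downstream weights before normalization", {
  # scaling the score (hence the gradients) by lambda scales L by lambda
  set.seed(13)
  A <- array(abs(rnorm(48)), dim = c(4, 4, 3))
  dA <- array(rnorm(48), dim = c(4, 4, 3))
  lam <- 3.7
  r1 <- gradcam_from_gradients(A, dA)
  r2 <- gradcam_from_gradients(A, lam * dA)
  expect_equal(r2$map, lam * r1$map, tolerance = 1e-12)
  expect_equal(r2$upsampled_map, r1$upsampled_map, tolerance = 1e-12)
})

test_that("model-level Grad-CAM gradients match finite differences", {
  # the acceptance-grade gradient check lives in test-acceptance.R; here a
  # single fitted-model case ties gradcam() to the head backward pass
  m <- small_model()
  A <- m$features[[1]]$A
  cam <- gradcam(m, A, class_index = 1)
  expect_equal(dim(cam$map), dim(A)[1:2])
  expect_equal(dim(cam$upsampled_map), c(224, 224))
  # alpha is the spatial mean of the gradient per channel
  expect_equal(cam$weights,
               vapply(seq_len(dim(A)[3]),
                      function(k) mean(cam$gradients[, , k]), 0))
  expect_error(gradcam(m, "nonsense"), "unsupported")
})

test_that("heatmap_to_boxes recovers rectangles and ranks blobs by mass", {
  map <- matrix(0, 50, 60)
  map[10:19, 20:29] <- 1
  b <- heatmap_to_boxes(map, tau = 0.5, max_regions = 2, min_area = 5)
  expect_length(b, 1)
  expect_equal(unclass(b[[1]]), list(x0 = 19, y0 = 9, x1 = 29, y1 = 19))

  # two blobs: keep the one with larger summed activation
  map2 <- matrix(0, 50, 60)
  map2[5:9, 5:9] <- 1.0        # mass 25
  map2[30:42, 30:42] <- 0.8    # mass 135.2
  b2 <- heatmap_to_boxes(map2, tau = 0.5, max_regions = 1, min_area = 5)
  expect_length(b2, 1)
  expect_equal(b2[[1]]$x0, 29)
  # both kept when allowed, ordered by mass
  b3 <- heatmap_to_boxes(map2, tau = 0.5, max_regions = 2, min_area = 5)
  expect_equal(b3[[1]]$x0, 29)
  expect_equal(b3[[2]]$x0, 4)

  # degenerate cases
  expect_equal(heatmap_to_boxes(matrix(0, 10, 10)), list())
  expect_length(heatmap_to_boxes(map2, tau = 0.5, max_regions = 2,
                                 min_area = 1000), 0)
  expect_error(heatmap_to_boxes(map, tau = 0), "tau")
})

test_that("box extraction is invariant to monotone rescaling of the map", {
  set.seed(33)
  map <- matrix(runif(224 * 224), 224, 224)
  map[100:150, 40:90] <- map[100:150, 40:90] + 2
  b1 <- heatmap_to_boxes(map, tau = 0.5, max_regions = 2)
  b2 <- heatmap_to_boxes(0.25 * map, tau = 0.5, max_regions = 2)
  expect_equal(b1, b2)
})

test_that("8-connected components merge diagonal neighbours", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE # a diagonal chain
  lab <- heartcam:::label_components(m)
  expect_equal(max(lab), 1)
  m[6, 6] <- TRUE
  expect_equal(max(heartcam:::label_components(m)), 2)
})

test_that("overlay PNG renders boxes on the image", {
  m <- small_model()
  cy <- m$data[[1]]
  img <- mel_spectrogram(butterworth_lowpass(cy$waveform, cy$sampling_rate),
                         cy$sampling_rate)
  cam <- gradcam(m, m$features[[1]]$A, class_index = 1)
  gt <- phases_to_gt_boxes(cy, m$features[[1]]$geometry)
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay_png(img, cam, gt$boxes, list(bounding_box(10, 10, 40, 60)), f)
  arr <- png::readPNG(f)
  expect_equal(dim(arr), c(224, 224, 3))
})
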