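test_that("SE block reproduces the squeeze/excite/reweight arithmetic", {
  set.seed(71)
  U <- array(rnorm(5 * 4 * 8), dim = c(5, 4, 8))
  p <- se_params(8, ratio = 4, seed = 3)
  out <- se_block(U, p)
  # independent elementwise recomputation with plain loops
  z <- vapply(1:8, function(c) mean(U[, , c]), 0)
  h1 <- pmax(as.numeric(p$W1 %*% z + p$b1), 0)
  s <- 1 / (1 + exp(-as.numeric(p$W2 %*% h1 + p$b2)))
  expected <- U
  for (c in 1:8) expected[, , c] <- s[c] * U[, , c]
  expect_lt(max(abs(out - expected)), 1e-6)
  # gates are strictly inside (0,1): output norms strictly below input norms
  expect_true(all(s > 0 & s < 1))
  for (c in 1:8) {
    expect_lt(sqrt(sum(out[, , c]^2)), sqrt(sum(U[, , c]^2)) + 1e-12)
  }
})

test_that("SE squeeze of constant channels returns the constants; zero in, zero out", {
  vals <- c(2, -1, 0.5, 3)
  U <- array(0, dim = c(3, 3, 4))
  for (c in 1:4) U[, , c] <- vals[c]
  fw <- heartcam:::se_forward(U, se_params(4, ratio = 2, seed = 1))
  expect_equal(fw$cache$z, vals)
  # all-zero input with zero biases: s = sigmoid(0) = 0.5, output all zero
  p0 <- se_params(4, ratio = 2, seed = 1)
  fz <- heartcam:::se_forward(array(0, dim = c(3, 3, 4)), p0)
  expect_equal(fz$cache$s, rep(0.5, 4))
  expect_true(all(fz$out == 0))
  expect_error(se_block(U, se_params(16, seed = 1)), "channels")
})

test_that("multi-head attention matches the hand-computed two-token case", {
  # tokens (1,0) and (0,1); identity projections; one head; d_k = 2
  A <- array(c(1, 0, 0, 1), dim = c(1, 2, 2))
  p <- list(Wq = array(diag(2), c(2, 2, 1)), Wk = array(diag(2), c(2, 2, 1)),
            Wv = array(diag(2), c(2, 2, 1)), Wo = diag(2))
  res <- mha_block(A, p, return_attention = TRUE)
  w11 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(res$attention[[1]][1, 1], w11, tolerance = 1e-4)
  expect_equal(round(w11, 4), 0.6698)
  out_tok1 <- c(res$out[1, 1, 1], res$out[1, 1, 2])
  expect_equal(out_tok1, c(w11, 1 - w11), tolerance = 1e-4)
  expect_equal(round(out_tok1, 4), c(0.6698, 0.3302))
})

test_that("attention rows are probability vectors and shape is preserved", {
  set.seed(88)
  F <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  p <- mha_params(8, n_heads = 3, d_k = 5, seed = 4)
  res <- mha_block(F, p, return_attention = TRUE)
  expect_equal(dim(res$out), dim(F))
  for (P in res$attention) {
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
  }
  expect_error(mha_params(8, d_k = 0), "d_k")
})

test_that("head backward passes match central finite differences", {
  # covers dense tail, dropout-free eval path, SE gating, attention and
  # batch-norm backward, and the GAP spreading
  for (variant in c("baseline", "se", "mha")) {
    case <- random_head_case(500 + match(variant, c("baseline", "se", "mha")),
                             variant)
    g <- head_logit_grad(case, case$A, class_index = 2)
    set.seed(9)
    idx <- sample(length(case$A), 25)
    h <- 1e-4
    for (k in idx) {
      Ap <- case$A; Ap[k] <- Ap[k] + h
      Am <- case$A; Am[k] <- Am[k] - h
      fd <- (head_logit(case, Ap, 2) - head_logit(case, Am, 2)) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-3 * max(abs(fd), 1e-4))
    }
  }
})

test_that("identity-style spatial blocks reduce to the baseline head", {
  # with the SE gate forced to 1 and the attention replaced by identity,
  # the three variants share the same GAP + dense tail arithmetic
  case_b <- random_head_case(600, "baseline")
  fw <- heartcam:::head_forward(case_b$params, case_b$head, list(case_b$A),
                                FALSE, NULL)
  G <- colMeans(matrix(case_b$A, ncol = 8))
  tf <- heartcam:::tail_forward(matrix(G, 1), case_b$params$tail, NULL,
                                FALSE, 0, FALSE)
  expect_equal(fw$logits, tf$logits)
})
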