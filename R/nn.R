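# Minimal neural-network engine (base R matrix algebra).
#
# Only what the classifier heads need: dense layers, ReLU, dropout,
# Gaussian noise, batch normalization, global average pooling, softmax
# cross-entropy, the squeeze-and-excitation block, multi-head self-attention
# over feature-map tokens, and an Adam optimizer.  Feature maps are
# H x W x C arrays; token matrices are (H*W) x C with column-major
# flattening of the spatial grid.

he_init <- function(nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

xavier_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(1 / nrow)), nrow, ncol)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

relu <- function(x) pmax(x, 0)

feature_to_tokens <- function(A) {
  d <- dim(A)
  matrix(A, nrow = d[1] * d[2], ncol = d[3])
}

tokens_to_feature <- function(X, h, w) {
  array(X, dim = c(h, w, ncol(X)))
}

# ---- squeeze and excitation -------------------------------------------------

#' Initialize squeeze-and-excitation parameters
#'
#' Two fully connected layers with a bottleneck of width
#' `max(ceiling(C/ratio), 4)`; weights He/Xavier initialized, biases zero.
#'
#' @param channels number of feature-map channels C.
#' @param ratio reduction ratio r of the bottleneck.
#' @param seed integer seed for the weight draw.
#' @return list with `W1` (bottleneck x C), `b1`, `W2` (C x bottleneck),
#'   `b2`.
#' @export
se_params <- function(channels, ratio = 16, seed = 1L) {
  bott <- max(ceiling(channels / ratio), 4)
  with_seed(seed, list(
    W1 = he_init(bott, channels, fan_in = channels),
    b1 = numeric(bott),
    W2 = xavier_init(channels, bott),
    b2 = numeric(channels)))
}

se_forward <- function(A, p) {
  d <- dim(A)
  hw <- d[1] * d[2]
  X <- feature_to_tokens(A)           # hw x C
  z <- colMeans(X)                    # squeeze: spatial mean per channel
  a1 <- as.numeric(p$W1 %*% z + p$b1)
  h1 <- relu(a1)
  a2 <- as.numeric(p$W2 %*% h1 + p$b2)
  s <- 1 / (1 + exp(-a2))             # excitation weights in (0,1)
  Y <- sweep(X, 2, s, "*")            # reweight channels
  list(out = tokens_to_feature(Y, d[1], d[2]),
       cache = list(X = X, z = z, a1 = a1, h1 = h1, s = s, dims = d))
}

se_backward <- function(dOut, cache, p) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dY <- feature_to_tokens(dOut)
  ds <- colSums(dY * cache$X)
  dX <- sweep(dY, 2, cache$s, "*")
  da2 <- ds * cache$s * (1 - cache$s)
  dh1 <- as.numeric(t(p$W2) %*% da2)
  da1 <- dh1 * (cache$a1 > 0)
  dz <- as.numeric(t(p$W1) %*% da1)
  dX <- dX + matrix(dz, nrow = hw, ncol = d[3], byrow = TRUE) / hw
  grads <- list(W1 = outer(da1, cache$z), b1 = da1,
                W2 = outer(da2, cache$h1), b2 = da2)
  list(dA = tokens_to_feature(dX, d[1], d[2]), grads = grads)
}

#' Apply a squeeze-and-excitation block to a feature map
#'
#' Squeeze: global average pooling of each channel.  Excite: a two-layer
#' gating network with ReLU then sigmoid produces per-channel weights in
#' (0,1).  Reweight: each channel is scaled by its weight.
#'
#' @param U feature map, `H x W x C` array.
#' @param params parameters from [se_params()] (shapes must match C).
#' @return recalibrated `H x W x C` array.
#' @export
se_block <- function(U, params) {
  stopifnot(length(dim(U)) == 3)
  if (ncol(params$W1) != dim(U)[3]) {
    stop("params shaped for ", ncol(params$W1), " channels; feature map has ",
         dim(U)[3])
  }
  se_forward(U, params)$out
}

# ---- multi-head self-attention ---------------------------------------------

#' Initialize multi-head attention parameters
#'
#' Per-head query/key/value projections `C x d_k` (`C x d_v` for values) and
#' an output projection `(h*d_v) x C`.
#'
#' @param channels token dimension C (feature-map channels).
#' @param n_heads number of heads h.
#' @param d_k key/query dimension per head.
#' @param d_v value dimension per head (defaults to `d_k`).
#' @param seed integer seed.
#' @return list with arrays `Wq`, `Wk` (`C x d_k x h`), `Wv` (`C x d_v x h`)
#'   and matrix `Wo` (`h*d_v x C`).
#' @export
mha_params <- function(channels, n_heads = 8, d_k = 128, d_v = d_k,
                       seed = 1L) {
  if (d_k <= 0) stop("d_k must be positive")
  with_seed(seed, {
    Wq <- array(stats::rnorm(channels * d_k * n_heads, sd = sqrt(1 / channels)),
                dim = c(channels, d_k, n_heads))
    Wk <- array(stats::rnorm(channels * d_k * n_heads, sd = sqrt(1 / channels)),
                dim = c(channels, d_k, n_heads))
    Wv <- array(stats::rnorm(channels * d_v * n_heads, sd = sqrt(1 / channels)),
                dim = c(channels, d_v, n_heads))
    Wo <- xavier_init(n_heads * d_v, channels)
    list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo)
  })
}

mha_forward <- function(A, p) {
  d <- dim(A)
  X <- feature_to_tokens(A)                 # n x C
  n <- nrow(X)
  if (n == 0) stop("feature map has zero tokens")
  h <- dim(p$Wq)[3]
  d_k <- dim(p$Wq)[2]
  d_v <- dim(p$Wv)[2]
  heads <- vector("list", h)
  O <- matrix(0, n, h * d_v)
  for (i in seq_len(h)) {
    Q <- X %*% p$Wq[, , i]
    K <- X %*% p$Wk[, , i]
    V <- X %*% p$Wv[, , i]
    P <- softmax_rows(Q %*% t(K) / sqrt(d_k))
    Oi <- P %*% V
    O[, ((i - 1) * d_v + 1):(i * d_v)] <- Oi
    heads[[i]] <- list(Q = Q, K = K, V = V, P = P)
  }
  Y <- O %*% p$Wo
  list(out = tokens_to_feature(Y, d[1], d[2]),
       cache = list(X = X, O = O, heads = heads, dims = d,
                    d_k = d_k, d_v = d_v))
}

mha_backward <- function(dOut, cache, p) {
  d <- cache$dims
  dY <- feature_to_tokens(dOut)
  X <- cache$X
  h <- length(cache$heads)
  d_k <- cache$d_k; d_v <- cache$d_v
  grads <- list(Wq = array(0, dim(p$Wq)), Wk = array(0, dim(p$Wk)),
                Wv = array(0, dim(p$Wv)), Wo = t(cache$O) %*% dY)
  dO <- dY %*% t(p$Wo)
  dX <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(h)) {
    hc <- cache$heads[[i]]
    dOi <- dO[, ((i - 1) * d_v + 1):(i * d_v), drop = FALSE]
    dP <- dOi %*% t(hc$V)
    dV <- t(hc$P) %*% dOi
    dS <- hc$P * (dP - rowSums(dP * hc$P))
    dQ <- dS %*% hc$K / sqrt(d_k)
    dK <- t(dS) %*% hc$Q / sqrt(d_k)
    grads$Wq[, , i] <- t(X) %*% dQ
    grads$Wk[, , i] <- t(X) %*% dK
    grads$Wv[, , i] <- t(X) %*% dV
    dX <- dX + dQ %*% t(p$Wq[, , i]) + dK %*% t(p$Wk[, , i]) +
      dV %*% t(p$Wv[, , i])
  }
  list(dA = tokens_to_feature(dX, d[1], d[2]), grads = grads)
}

#' Apply multi-head self-attention to a feature map
#'
#' The `H x W x C` map is reshaped to `H*W` tokens of dimension C;
#' scaled dot-product self-attention (`softmax(Q K' / sqrt(d_k)) V`) is
#' computed per head with learned projections, heads are concatenated,
#' projected back to C, and reshaped to `H x W x C`.
#'
#' @param F feature map, `H x W x C` array.
#' @param params parameters from [mha_params()] (or hand-built of the same
#'   shapes).
#' @param return_attention also return the per-head attention matrices.
#' @return the attended `H x W x C` array, or (with
#'   `return_attention = TRUE`) a list `out`, `attention` (list of
#'   `H*W x H*W` row-stochastic matrices).
#' @export
mha_block <- function(F, params, return_attention = FALSE) {
  stopifnot(length(dim(F)) == 3)
  fw <- mha_forward(F, params)
  if (return_attention) {
    list(out = fw$out, attention = lapply(fw$cache$heads, `[[`, "P"))
  } else {
    fw$out
  }
}

# ---- dense tail layers ------------------------------------------------------

dense_init <- function(sizes, n_in, n_out, use_bn, seed) {
  with_seed(seed, {
    dims <- c(n_in, sizes, n_out)
    layers <- vector("list", length(dims) - 1)
    for (i in seq_along(layers)) {
      layers[[i]] <- list(W = he_init(dims[i], dims[i + 1], fan_in = dims[i]),
                          b = numeric(dims[i + 1]))
      if (use_bn && i < length(layers)) {
        layers[[i]]$gamma <- rep(1, dims[i + 1])
        layers[[i]]$beta <- numeric(dims[i + 1])
      }
    }
    layers
  })
}

bn_forward <- function(Z, gamma, beta, state, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  xhat <- sweep(sweep(Z, 2, mu), 2, sqrt(va + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, cache = list(xhat = xhat, va = va, eps = eps,
                               gamma = gamma, m = nrow(Z),
                               training = training),
       state = state)
}

bn_backward <- function(dOut, cache) {
  m <- cache$m
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, cache$gamma, "*")
  inv_std <- 1 / sqrt(cache$va + cache$eps)
  if (cache$training) {
    # batch statistics depend on Z: full batch-norm backward
    dZ <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dOut),
                               byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), m, ncol(dOut),
                                byrow = TRUE),
                2, inv_std, "*")
  } else {
    # evaluation mode: running statistics are constants, BN is affine
    dZ <- sweep(dxhat, 2, inv_std, "*")
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Dense tail forward over a batch matrix G (B x n_in).  Two flavours:
# dropout after ReLU (baseline / SE heads) or batch normalization between
# the affine map and ReLU (MHA head).  The last layer is affine (logits).
tail_forward <- function(G, layers, bn_states, training, dropout_rate,
                         use_bn) {
  n_lay <- length(layers)
  caches <- vector("list", n_lay)
  Z <- G
  for (i in seq_len(n_lay)) {
    lay <- layers[[i]]
    Zin <- Z
    A <- sweep(Zin %*% lay$W, 2, lay$b, "+")
    if (i < n_lay) {
      if (use_bn) {
        bn <- bn_forward(A, lay$gamma, lay$beta, bn_states[[i]], training)
        bn_states[[i]] <- bn$state
        H <- relu(bn$out)
        caches[[i]] <- list(Zin = Zin, A = A, bn = bn$cache,
                            relu_mask = bn$out > 0)
        Z <- H
      } else {
        H <- relu(A)
        mask <- NULL
        if (training && dropout_rate > 0) {
          mask <- matrix(stats::runif(length(H)) >= dropout_rate,
                         nrow(H), ncol(H)) / (1 - dropout_rate)
          H <- H * mask
        }
        caches[[i]] <- list(Zin = Zin, A = A, mask = mask)
        Z <- H
      }
    } else {
      caches[[i]] <- list(Zin = Zin)
      Z <- A
    }
  }
  list(logits = Z, caches = caches, bn_states = bn_states)
}

tail_backward <- function(dLogits, layers, caches, use_bn) {
  n_lay <- length(layers)
  grads <- vector("list", n_lay)
  dZ <- dLogits
  for (i in rev(seq_len(n_lay))) {
    lay <- layers[[i]]
    ca <- caches[[i]]
    if (i < n_lay) {
      if (use_bn) {
        dH <- dZ * ca$relu_mask
        bb <- bn_backward(dH, ca$bn)
        dA <- bb$dZ
        grads[[i]] <- list(W = t(ca$Zin) %*% dA, b = colSums(dA),
                           gamma = bb$dgamma, beta = bb$dbeta)
      } else {
        dH <- dZ
        if (!is.null(ca$mask)) dH <- dH * ca$mask
        dA <- dH * (ca$A > 0)
        grads[[i]] <- list(W = t(ca$Zin) %*% dA, b = colSums(dA))
      }
    } else {
      dA <- dZ
      grads[[i]] <- list(W = t(ca$Zin) %*% dA, b = colSums(dA))
    }
    dZ <- dA %*% t(lay$W)
  }
  list(grads = grads, dG = dZ)
}

# ---- Adam -------------------------------------------------------------------

# params/grads are arbitrarily nested lists of numeric arrays with matching
# structure.
adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- names(p) %||% seq_along(p)
      for (k in keys) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two nested grad lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- grads_add(a[[k]], b[[k]])
    return(a)
  }
  a + b
}

grads_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grads_scale, s = s))
  a * s
}

# softmax cross-entropy over a batch; y is an integer class vector (1-based)
softmax_xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  dLogits <- P
  dLogits[cbind(seq_len(n), y)] <- dLogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = P, dLogits = dLogits / n)
}
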