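# Internal numerical / reproducibility helpers.

#' Derive a child seed from a parent seed and a stream label
#'
#' All randomness in the package flows through seeds derived from a single
#' user-supplied integer, so any stage (dataset, split, init, selection, ...)
#' can be re-seeded in isolation.  The derivation is a small multiplicative
#' congruential mix over the label's bytes; results stay in `[1, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param ... character or integer tokens naming the substream.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (tok in list(...)) {
    bytes <- if (is.character(tok)) as.integer(charCodeAt(tok)) else as.integer(tok)
    for (b in bytes) {
      s <- (s * 69069 + b + 1) %% m
    }
  }
  as.integer(if (s < 1) 1 else s)
}

charCodeAt <- function(x) utf8ToInt(paste(as.character(x), collapse = "|"))

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable bilinear resize of a matrix, pixel-center aligned
# (destination pixel centers are mapped linearly onto source pixel centers,
# edges clamped).  Used to bring mel spectrograms to the 224x224 image grid
# and to upsample Grad-CAM maps.
resize_bilinear <- function(m, out_rows, out_cols) {
  stopifnot(is.matrix(m), out_rows >= 1, out_cols >= 1)
  interp_matrix <- function(n_out, n_in) {
    if (n_in == 1) {
      return(matrix(1, n_out, 1))
    }
    # centers: source coordinate for output pixel i (1-based centers)
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    s <- clamp(s, 1, n_in)
    lo <- pmin(floor(s), n_in - 1)
    w <- s - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo)] <- 1 - w
    A[cbind(seq_len(n_out), lo + 1)] <- A[cbind(seq_len(n_out), lo + 1)] + w
    A
  }
  Ri <- interp_matrix(out_rows, nrow(m))
  Rj <- interp_matrix(out_cols, ncol(m))
  Ri %*% m %*% t(Rj)
}

# Label 8-connected components of a logical matrix.  Returns an integer
# matrix; 0 = background, components numbered 1..n (arbitrary order).
# Implemented as vectorized max-label propagation over the 8 neighbour
# shifts until fixpoint.
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, di, dj) {
    out <- matrix(0L, h, w)
    ri <- seq_len(h) - di; rj <- seq_len(w) - dj
    keep_i <- ri >= 1 & ri <= h; keep_j <- rj >= 1 & rj <= w
    out[keep_i, keep_j] <- m[ri[keep_i], rj[keep_j]]
    out
  }
  repeat {
    nb <- lab
    for (di in -1:1) {
      for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        nb <- pmax(nb, shift(lab, di, dj))
      }
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  # renumber 1..k
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

# FNV-1a hash of a character scalar, returned as hex string.  Used for
# content-addressed stage caching in the pipeline manifest (no cryptographic
# requirement).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    # (hi*2^16 + lo) * p mod 2^32, kept within double precision
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(x) fnv1a(paste(deparse(x), collapse = "\n"))

`%||%` <- function(a, b) if (is.null(a)) b else a
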