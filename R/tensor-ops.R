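# Low-level tensor primitives. A feature grid is a numeric array
# dim c(H, W, C); a batch stacks grids along a fourth axis, dim c(H, W, C, B).
# Every *_forward() returns list(out, cache, ...) and the matching
# *_backward() consumes the cache and an upstream gradient of the output's
# shape, returning gradients for the input and every parameter.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so library calls never perturb a
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible child seed from a base seed and an index, kept
# inside the 32-bit signed range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 65011 * 31847 + as.double(index) * 7919 + 11) %%
    2147483647)
}

# He-normal initialization: N(0, sqrt(2 / fan_in)), the variance-scaled
# scheme used for all convolution and dense weights.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), mean = 0, sd = sqrt(2 / fan_in)), dim = dims)
}

as_grid <- function(x, what = "feature grid") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(what, " must be a 3-d array (H x W x C)", call. = FALSE)
  }
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  x
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- 2-d convolution --------------------------------------------------------

conv_out_len <- function(n, k, stride, dilation, pad) {
  eff <- dilation * (k - 1L) + 1L
  (n + 2L * pad - eff) %/% stride + 1L
}

# Same-padding for odd kernels keeps H, W; padding = "valid" is used by the
# 2x2 stride-2 downsampling convolution. The im2col + GEMM work happens in
# the compiled kernels; the backward pass re-derives the patch matrix from
# the cached input rather than storing it.
conv2d_forward <- function(x, w, b, stride = 1L, dilation = 1L,
                           padding = c("same", "valid"), cache = FALSE) {
  padding <- match.arg(padding)
  x <- as_batch(x)
  d <- dim(x)
  kd <- dim(w)
  if (d[3] != kd[3]) {
    stop("conv2d: input has ", d[3], " channels but kernel expects ", kd[3],
      call. = FALSE
    )
  }
  if (stride == 2L && padding[1] == "valid" &&
    (d[1] %% 2L != 0L || d[2] %% 2L != 0L)) {
    stop("stride-2 downsampling requires even spatial dims (got ",
      d[1], " x ", d[2], ")",
      call. = FALSE
    )
  }
  ph <- if (padding == "same") dilation * (kd[1] - 1L) %/% 2L else 0L
  pw <- if (padding == "same") dilation * (kd[2] - 1L) %/% 2L else 0L
  ho <- conv_out_len(d[1], kd[1], stride, dilation, ph)
  wo <- conv_out_len(d[2], kd[2], stride, dilation, pw)
  if (ho < 1L || wo < 1L) stop("conv2d: input smaller than kernel", call. = FALSE)
  out <- .conv2d_fwd(
    x, as.integer(d), w, as.integer(kd), as.numeric(b),
    as.integer(stride), as.integer(dilation), ph, pw, ho, wo
  )
  list(
    out = out,
    cache = if (cache) {
      list(
        x = x, w = w, dims = d, kdims = kd, stride = as.integer(stride),
        dilation = as.integer(dilation), ph = ph, pw = pw, ho = ho, wo = wo
      )
    }
  )
}

conv2d_backward <- function(cache, dout) {
  .conv2d_bwd(
    cache$x, as.integer(cache$dims), cache$w, as.integer(cache$kdims),
    as_batch(dout), cache$stride, cache$dilation, cache$ph, cache$pw,
    cache$ho, cache$wo
  )
}

# ---- 2x2 stride-2 transposed convolution -----------------------------------

convtranspose2_forward <- function(x, w, b, cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  kd <- dim(w) # (2, 2, Cin, Cout)
  n <- d[1] * d[2]
  out <- array(0, dim = c(2L * d[1], 2L * d[2], kd[4], d[4]))
  xm_list <- if (cache) vector("list", d[4]) else NULL
  for (bi in seq_len(d[4])) {
    xm <- matrix(x[, , , bi], n, d[3])
    o3 <- array(0, dim = c(2L * d[1], 2L * d[2], kd[4]))
    for (dj in 0:1) {
      for (di in 0:1) {
        yb <- xm %*% matrix(w[di + 1L, dj + 1L, , ], d[3], kd[4])
        o3[
          seq.int(1L + di, by = 2L, length.out = d[1]),
          seq.int(1L + dj, by = 2L, length.out = d[2]),
        ] <- array(yb, dim = c(d[1], d[2], kd[4]))
      }
    }
    o3 <- o3 + rep(b, each = 4L * n)
    out[, , , bi] <- o3
    if (cache) xm_list[[bi]] <- xm
  }
  list(out = out, cache = if (cache) list(xm = xm_list, dims = d, kdims = kd, w = w))
}

convtranspose2_backward <- function(cache, dout) {
  dout <- as_batch(dout)
  d <- cache$dims
  kd <- cache$kdims
  n <- d[1] * d[2]
  dw <- array(0, dim = kd)
  db <- numeric(kd[4])
  dx <- array(0, dim = d)
  for (bi in seq_len(d[4])) {
    dy3 <- dout[, , , bi, drop = TRUE]
    if (length(dim(dy3)) == 2L) dim(dy3) <- c(dim(dy3), 1L)
    db <- db + colSums(matrix(dy3, 4L * n, kd[4]))
    xm <- cache$xm[[bi]]
    dxm <- matrix(0, n, d[3])
    for (dj in 0:1) {
      for (di in 0:1) {
        dyb <- matrix(
          dy3[
            seq.int(1L + di, by = 2L, length.out = d[1]),
            seq.int(1L + dj, by = 2L, length.out = d[2]), ,
            drop = FALSE
          ],
          n, kd[4]
        )
        wm <- matrix(cache$w[di + 1L, dj + 1L, , ], d[3], kd[4])
        dxm <- dxm + dyb %*% t(wm)
        dw[di + 1L, dj + 1L, , ] <- dw[di + 1L, dj + 1L, , ] +
          crossprod(xm, dyb)
      }
    }
    dx[, , , bi] <- dxm
  }
  list(dx = dx, dw = dw, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_params <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch))
}

bn_state <- function(ch) {
  list(mean = rep(0, ch), var = rep(1, ch))
}

# Training mode normalizes with the statistics of the current batch (biased
# variance) and updates the running moments; inference mode uses the stored
# running moments so outputs are deterministic. Internally the (H, W, C, B)
# block is viewed as an (H*W) x (C*B) matrix (channel fastest across
# columns), so per-channel statistics are per-column sums folded over the
# batch — no axis permutation is needed.
bn_colstat <- function(colsums, ch, nb) .rowSums(matrix(colsums, ch, nb), ch, nb)

bn_forward <- function(x, p, st, training = FALSE, momentum = 0.9,
                       eps = 1e-5, cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  xm <- matrix(x, hw, d[3] * d[4])
  if (training) {
    mu <- bn_colstat(.colSums(xm, hw, d[3] * d[4]), d[3], d[4]) / m
    v <- bn_colstat(.colSums(xm * xm, hw, d[3] * d[4]), d[3], d[4]) / m - mu^2
    v <- pmax(v, 0)
    st$mean <- momentum * st$mean + (1 - momentum) * mu
    st$var <- momentum * st$var + (1 - momentum) * v
  } else {
    mu <- st$mean
    v <- st$var
  }
  inv_std <- 1 / sqrt(v + eps)
  colrep <- function(vec) rep(rep(vec, d[4]), each = hw)
  scale <- p$gamma * inv_std
  shift <- p$beta - mu * scale
  ym <- xm * colrep(scale) + colrep(shift)
  out <- array(ym, dim = d)
  list(
    out = out, state = st,
    cache = if (cache) {
      list(
        xm = xm, mu = mu, inv_std = inv_std, gamma = p$gamma, dims = d,
        training = training
      )
    }
  )
}

bn_backward <- function(cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  m <- hw * d[4]
  ch <- d[3]
  nb <- d[4]
  colrep <- function(vec) rep(rep(vec, nb), each = hw)
  dym <- matrix(as_batch(dout), hw, ch * nb)
  xhat <- (cache$xm - colrep(cache$mu)) * colrep(cache$inv_std)
  dgamma <- bn_colstat(.colSums(dym * xhat, hw, ch * nb), ch, nb)
  dbeta <- bn_colstat(.colSums(dym, hw, ch * nb), ch, nb)
  if (cache$training) {
    dxm <- (dym * colrep(cache$gamma) -
      colrep(dbeta * cache$gamma / m) -
      xhat * colrep(dgamma * cache$gamma / m)) * colrep(cache$inv_std)
  } else {
    dxm <- dym * colrep(cache$gamma * cache$inv_std)
  }
  list(dx = array(dxm, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ------------------------------------------------------------

relu_forward <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = x > 0)
}

relu_backward <- function(cache, dout) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

sigmoid_forward <- function(x) {
  s <- sigmoid(x)
  list(out = s, cache = s)
}

sigmoid_backward <- function(cache, dout) dout * cache * (1 - cache)

# ---- parameter-tree helpers -------------------------------------------------

# Model parameters live in nested named lists of numeric arrays; these
# helpers apply a function leaf-wise across one or two identically shaped
# trees (used by the optimizer and gradient accumulation). Non-numeric
# leaves (e.g. logical structure flags) are passed through untouched.
tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(el) tree_map(f, el))
    names(out) <- names(a)
    out
  } else if (is.numeric(a)) {
    f(a)
  } else {
    a
  }
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y),
      a, b,
      SIMPLIFY = FALSE
    )
    names(out) <- names(a)
    out
  } else if (is.numeric(a)) {
    f(a, b)
  } else {
    a
  }
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_count <- function(a) {
  if (is.list(a)) {
    sum(vapply(a, tree_count, numeric(1)))
  } else if (is.numeric(a)) {
    length(a)
  } else {
    0
  }
}

# Flatten a parameter tree into a named numeric vector (used for checksums
# and finite-difference testing).
tree_flatten <- function(a, prefix = "") {
  if (is.list(a)) {
    nms <- names(a)
    if (is.null(nms)) nms <- as.character(seq_along(a))
    nms[nms == ""] <- as.character(seq_along(a))[nms == ""]
    parts <- mapply(
      function(el, nm) tree_flatten(el, paste0(prefix, nm, ".")),
      a, nms,
      SIMPLIFY = FALSE
    )
    unlist(parts, use.names = TRUE)
  } else if (!is.numeric(a)) {
    NULL
  } else {
    v <- as.numeric(a)
    names(v) <- paste0(sub("\\.$", "", prefix), "[", seq_along(v), "]")
    v
  }
}
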