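# Attention blocks used on the skip connections. All cores operate on a
# single feature grid (H x W x C); the network module loops them over a
# batch because every statistic they use (pooling, softmax affinity) is
# per-image. Public wrappers validate shapes and hide the caches.

#' Create parameters for the positional convolutional block attention module
#'
#' Bundles the three sub-blocks gating a skip connection: channel attention
#' (shared two-layer bottleneck MLP over global average/max pooled channel
#' descriptors), spatial attention (channel-wise average/max maps, optional
#' per-position dense layers, then a dilated 7x7 convolution) and position
#' attention (1x1 query/key/value projections with a softmax affinity over
#' all pixel pairs, scaled by a learnable `alpha` initialized at 0).
#'
#' @param channels Number of channels `C` of the gated feature grid.
#' @param reduction Bottleneck reduction ratio of the channel MLP; the
#'   hidden width is `max(1, floor(C / reduction))`. Default 8.
#' @param sam_dense Include the per-position dense (1x1) layers on the
#'   pooled maps inside spatial attention. Default `TRUE`.
#' @param pam_reduction Optional channel reduction of the query/key
#'   projections inside position attention; default `NULL` keeps all `C`
#'   channels.
#' @param init `"he"` for He-normal weights (biases zero) or `"zero"` for
#'   all-zero parameters (useful for algebraic fixtures).
#' @param seed Integer seed used when `init = "he"`.
#' @return A list with components `cam`, `sam`, `pam` holding the weights.
#' @export
pcbam_params <- function(channels, reduction = 8L, sam_dense = TRUE,
                         pam_reduction = NULL, init = c("he", "zero"),
                         seed = 1L) {
  init <- match.arg(init)
  list(
    cam = cam_params(channels, reduction, init, derive_seed(seed, 1L)),
    sam = sam_params(sam_dense, init, derive_seed(seed, 2L)),
    pam = pam_params(channels, pam_reduction, init, derive_seed(seed, 3L))
  )
}

cam_params <- function(channels, reduction = 8L, init = "he", seed = 1L) {
  hidden <- max(1L, channels %/% reduction)
  p <- if (init == "zero") {
    list(
      w1 = array(0, c(channels, hidden)), b1 = numeric(hidden),
      w2 = array(0, c(hidden, channels)), b2 = numeric(channels)
    )
  } else {
    with_seed(seed, list(
      w1 = he_init(c(channels, hidden), channels), b1 = numeric(hidden),
      w2 = he_init(c(hidden, channels), hidden), b2 = numeric(channels)
    ))
  }
  p
}

sam_params <- function(sam_dense = TRUE, init = "he", seed = 1L) {
  p <- if (init == "zero") {
    list(
      wa = 0, ba = 0, wm = 0, bm = 0,
      conv_w = array(0, c(7L, 7L, 2L, 1L)), conv_b = 0
    )
  } else {
    with_seed(seed, list(
      wa = stats::rnorm(1, 0, sqrt(2)), ba = 0,
      wm = stats::rnorm(1, 0, sqrt(2)), bm = 0,
      conv_w = he_init(c(7L, 7L, 2L, 1L), 7L * 7L * 2L), conv_b = 0
    ))
  }
  p$dense <- isTRUE(sam_dense)
  p
}

pam_params <- function(channels, pam_reduction = NULL, init = "he", seed = 1L) {
  ck <- if (is.null(pam_reduction)) {
    channels
  } else {
    max(1L, channels %/% as.integer(pam_reduction))
  }
  p <- if (init == "zero") {
    list(
      wb = array(0, c(channels, ck)), bb = numeric(ck),
      wz = array(0, c(channels, ck)), bz = numeric(ck),
      wd = array(0, c(channels, channels)), bd = numeric(channels),
      alpha = 0
    )
  } else {
    with_seed(seed, list(
      wb = he_init(c(channels, ck), channels), bb = numeric(ck),
      wz = he_init(c(channels, ck), channels), bz = numeric(ck),
      wd = he_init(c(channels, channels), channels), bd = numeric(channels),
      alpha = 0 # learnable residual scale, starts at zero by construction
    ))
  }
  p
}

grid_as_mat <- function(f) matrix(f, dim(f)[1] * dim(f)[2], dim(f)[3])

# ---- channel attention ------------------------------------------------------

cam_forward <- function(f, p, cache = FALSE) {
  fm <- grid_as_mat(f)
  gap <- colMeans(fm)
  imax <- max.col(t(fm), ties.method = "first") # argmax row per channel
  gmp <- fm[cbind(imax, seq_along(imax))]
  mlp_one <- function(v) {
    h_pre <- drop(v %*% p$w1) + p$b1
    h <- pmax(h_pre, 0)
    list(out = drop(h %*% p$w2) + p$b2, h = h, h_pre = h_pre)
  }
  ma <- mlp_one(gap)
  mm <- mlp_one(gmp)
  gate <- sigmoid(ma$out + mm$out)
  list(
    out = gate,
    cache = if (cache) {
      list(
        fm = fm, gap = gap, gmp = gmp, imax = imax, ma = ma, mm = mm,
        gate = gate, hw = dim(f)[1:2]
      )
    }
  )
}

cam_backward <- function(p, cache, dgate) {
  ds <- dgate * cache$gate * (1 - cache$gate)
  n <- nrow(cache$fm)
  ch <- ncol(cache$fm)
  back_one <- function(m, v) {
    dh <- drop(ds %*% t(p$w2)) * (m$h_pre > 0)
    list(
      dw2 = outer(m$h, ds), db2 = ds,
      dw1 = outer(v, dh), db1 = dh,
      dv = drop(dh %*% t(p$w1))
    )
  }
  ga <- back_one(cache$ma, cache$gap)
  gm <- back_one(cache$mm, cache$gmp)
  dfm <- matrix(rep(ga$dv / n, each = n), n, ch)
  dfm[cbind(cache$imax, seq_len(ch))] <-
    dfm[cbind(cache$imax, seq_len(ch))] + gm$dv
  list(
    df = array(dfm, dim = c(cache$hw, ch)),
    grads = list(
      w1 = ga$dw1 + gm$dw1, b1 = ga$db1 + gm$db1,
      w2 = ga$dw2 + gm$dw2, b2 = ga$db2 + gm$db2
    )
  )
}

# ---- spatial attention ------------------------------------------------------

sam_forward <- function(fc_prime, p, cache = FALSE) {
  d <- dim(fc_prime)
  fm <- grid_as_mat(fc_prime)
  avg <- rowMeans(fm)
  mx <- fm[, 1]
  if (d[3] > 1L) for (ci in 2:d[3]) mx <- pmax(mx, fm[, ci])
  amax <- max.col(fm, ties.method = "first") # winning channel per position
  a2 <- if (p$dense) p$wa * avg + p$ba else avg
  m2 <- if (p$dense) p$wm * mx + p$bm else mx
  pooled <- array(c(a2, m2), dim = c(d[1], d[2], 2L))
  cv <- conv2d_forward(pooled, p$conv_w, p$conv_b,
    stride = 1L, dilation = 4L,
    padding = "same", cache = cache
  )
  gate <- sigmoid(cv$out[, , , 1L])
  dim(gate) <- c(d[1], d[2], 1L)
  list(
    out = gate,
    cache = if (cache) {
      list(
        conv = cv$cache, gate = gate, avg = avg, mx = mx, amax = amax,
        dims = d
      )
    }
  )
}

sam_backward <- function(p, cache, dgate) {
  d <- cache$dims
  dpre <- dgate * cache$gate * (1 - cache$gate)
  cb <- conv2d_backward(cache$conv, array(dpre, dim = c(d[1], d[2], 1L, 1L)))
  dpooled <- array(cb$dx, dim = c(d[1] * d[2], 2L))
  da2 <- dpooled[, 1]
  dm2 <- dpooled[, 2]
  if (p$dense) {
    dwa <- sum(da2 * cache$avg)
    dba <- sum(da2)
    dwm <- sum(dm2 * cache$mx)
    dbm <- sum(dm2)
    davg <- da2 * p$wa
    dmx <- dm2 * p$wm
  } else {
    dwa <- dba <- dwm <- dbm <- 0
    davg <- da2
    dmx <- dm2
  }
  dfm <- matrix(davg / d[3], d[1] * d[2], d[3])
  dfm[cbind(seq_len(d[1] * d[2]), cache$amax)] <-
    dfm[cbind(seq_len(d[1] * d[2]), cache$amax)] + dmx
  list(
    df = array(dfm, dim = d),
    grads = list(
      wa = dwa, ba = dba, wm = dwm, bm = dbm,
      conv_w = cb$dw, conv_b = cb$db
    )
  )
}

# ---- CBAM -------------------------------------------------------------------

cbam_forward <- function(f, p, cache = FALSE) {
  d <- dim(f)
  ca <- cam_forward(f, p$cam, cache = cache)
  fcp <- f * rep(ca$out, each = d[1] * d[2])
  sa <- sam_forward(fcp, p$sam, cache = cache)
  sp <- as.vector(sa$out)
  out <- fcp * array(sp, dim = d) # gate broadcast over channels
  list(
    out = out,
    cache = if (cache) {
      list(cam = ca$cache, sam = sa$cache, fcp = fcp, sp = sp, f = f, dims = d)
    }
  )
}

cbam_backward <- function(p, cache, dout) {
  d <- cache$dims
  n <- d[1] * d[2]
  dout_m <- matrix(dout, n, d[3])
  fcp_m <- matrix(cache$fcp, n, d[3])
  dsp <- rowSums(dout_m * fcp_m)
  dfcp <- dout * array(cache$sp, dim = d)
  sb <- sam_backward(p$sam, cache$sam, array(dsp, dim = c(d[1], d[2], 1L)))
  dfcp <- dfcp + sb$df
  dfcp_m <- matrix(dfcp, n, d[3])
  fm <- matrix(cache$f, n, d[3])
  dgate <- colSums(dfcp_m * fm)
  cbk <- cam_backward(p$cam, cache$cam, dgate)
  df <- dfcp * rep(cache$cam$gate, each = n) + cbk$df
  list(df = df, grads = list(cam = cbk$grads, sam = sb$grads))
}

# ---- position attention -----------------------------------------------------

pam_project <- function(f, p) {
  fm <- grid_as_mat(f)
  list(
    fm = fm,
    bm = fm %*% p$wb + rep(p$bb, each = nrow(fm)),
    zm = fm %*% p$wz + rep(p$bz, each = nrow(fm)),
    dm = fm %*% p$wd + rep(p$bd, each = nrow(fm))
  )
}

# The affinity softmax over all pixel pairs runs through the compiled
# row-chunked kernels (.pam_attention_forward/backward), which never
# materialize the N x N matrix; the exact double-precision path below
# backs the user-facing position_affinity().

# Numerically guarded row softmax of a logit chunk. Softmax is invariant
# to per-row shifts, so subtracting the chunk-wide max suffices unless the
# spread is large enough to underflow whole rows, in which case the exact
# per-row max is used.
softmax_rows <- function(lg) {
  hi <- max(lg)
  if (hi - min(lg) > 600) {
    hi <- lg[cbind(seq_len(nrow(lg)), max.col(lg, ties.method = "first"))]
  }
  e <- exp(lg - hi)
  e / rowSums(e)
}

pam_forward <- function(f, p, cache = FALSE) {
  d <- dim(f)
  pr <- pam_project(f, p)
  att <- .pam_attention_forward(pr$zm, pr$bm, pr$dm)
  out <- array(p$alpha * att + pr$fm, dim = d)
  list(
    out = out,
    cache = if (cache) list(pr = pr, att = att, dims = d)
  )
}

pam_backward <- function(p, cache, dout) {
  d <- cache$dims
  pr <- cache$pr
  n <- nrow(pr$fm)
  dout_m <- matrix(dout, n, d[3])
  dalpha <- sum(dout_m * cache$att)
  da <- p$alpha * dout_m
  kb <- .pam_attention_backward(pr$zm, pr$bm, pr$dm, da)
  dbm <- kb$db
  dzm <- kb$dz
  ddm <- kb$dd
  dfm <- dout_m +
    dbm %*% t(p$wb) + dzm %*% t(p$wz) + ddm %*% t(p$wd)
  list(
    df = array(dfm, dim = d),
    grads = list(
      wb = crossprod(pr$fm, dbm), bb = colSums(dbm),
      wz = crossprod(pr$fm, dzm), bz = colSums(dzm),
      wd = crossprod(pr$fm, ddm), bd = colSums(ddm),
      alpha = dalpha
    )
  )
}

pcbam_forward <- function(f, p, cache = FALSE) {
  pa <- pam_forward(f, p$pam, cache = cache)
  cb <- cbam_forward(f, p, cache = cache)
  list(
    out = pa$out + cb$out,
    cache = if (cache) list(pam = pa$cache, cbam = cb$cache)
  )
}

pcbam_backward <- function(p, cache, dout) {
  pb <- pam_backward(p$pam, cache$pam, dout)
  cb <- cbam_backward(p, cache$cbam, dout)
  list(
    df = pb$df + cb$df,
    grads = list(cam = cb$grads$cam, sam = cb$grads$sam, pam = pb$grads)
  )
}

# ---- public API -------------------------------------------------------------

#' Channel attention gate
#'
#' Squeezes a feature grid to per-channel descriptors by global average and
#' max pooling, pushes both through a shared bottleneck MLP and returns the
#' sigmoid of their sum: one multiplicative weight in (0, 1) per channel.
#'
#' @param f Feature grid, numeric array `H x W x C`.
#' @param params Channel-attention parameters (`pcbam_params(...)$cam`).
#' @return Numeric vector of length `C` with entries strictly in (0, 1).
#' @export
channel_attention <- function(f, params) {
  f <- as_grid(f)
  if (dim(f)[3] != nrow(params$w1)) {
    stop("channel_attention: grid has ", dim(f)[3],
      " channels but params expect ", nrow(params$w1),
      call. = FALSE
    )
  }
  cam_forward(f, params)$out
}

#' Apply a channel gate to a feature grid
#'
#' Multiplies every spatial position of channel `c` by `gate[c]`.
#'
#' @param f Feature grid `H x W x C`.
#' @param gate Numeric vector of length `C`.
#' @return Gated grid of the same shape as `f`.
#' @export
apply_channel_gate <- function(f, gate) {
  f <- as_grid(f)
  if (length(gate) != dim(f)[3]) {
    stop("apply_channel_gate: gate length ", length(gate),
      " does not match ", dim(f)[3], " channels",
      call. = FALSE
    )
  }
  f * rep(gate, each = dim(f)[1] * dim(f)[2])
}

#' Spatial attention gate
#'
#' Pools the (already channel-gated) grid across channels into average and
#' max maps, optionally applies per-position dense layers, concatenates the
#' two maps and passes them through a 7x7 convolution with dilation 4
#' (same padding) and a sigmoid, yielding one weight in (0, 1) per pixel.
#'
#' @param fc_prime Feature grid `H x W x C`.
#' @param params Spatial-attention parameters (`pcbam_params(...)$sam`).
#' @return Gate array `H x W x 1`.
#' @export
spatial_attention <- function(fc_prime, params) {
  fc_prime <- as_grid(fc_prime)
  sam_forward(fc_prime, params)$out
}

#' Convolutional block attention (channel then spatial gating)
#'
#' Applies the channel gate to `f`, derives the spatial gate from the
#' result and multiplies it in, broadcast over channels.
#'
#' @param f Feature grid `H x W x C`.
#' @param params Parameter bundle from [pcbam_params()].
#' @return Attended grid of the same shape as `f`.
#' @export
cbam <- function(f, params) {
  f <- as_grid(f)
  cbam_forward(f, params)$out
}

#' Softmax affinity matrix of position attention
#'
#' Projects the grid to query/key maps with 1x1 convolutions and returns
#' the row-stochastic `N x N` matrix (`N = H * W`) whose entry `[j, i]` is
#' the softmax-normalized affinity of source position `i` to target `j`.
#' The full matrix is materialized, so this is intended for moderate grid
#' sizes; the network path uses a chunked evaluation instead.
#'
#' @param f Feature grid `H x W x C`.
#' @param params Position-attention parameters (`pcbam_params(...)$pam`).
#' @return `N x N` matrix with non-negative entries and unit row sums.
#' @export
position_affinity <- function(f, params) {
  f <- as_grid(f)
  pr <- pam_project(f, params)
  softmax_rows(tcrossprod(pr$zm, pr$bm))
}

#' Position attention
#'
#' Re-expresses every position as the affinity-weighted sum of the value
#' projection over all positions, scales it by the learnable `alpha`
#' (initialized at 0) and adds the input residually.
#'
#' @inheritParams position_affinity
#' @return Attended grid of the same shape as `f`.
#' @export
position_attention <- function(f, params) {
  f <- as_grid(f)
  pam_forward(f, params)$out
}

#' Positional convolutional block attention (PCBAM)
#'
#' Element-wise sum of the position-attention and CBAM transforms of the
#' same input grid.
#'
#' @param f Feature grid `H x W x C`.
#' @param params Parameter bundle from [pcbam_params()].
#' @return Attended grid of the same shape as `f`.
#' @export
pcbam <- function(f, params) {
  f <- as_grid(f)
  pcbam_forward(f, params)$out
}
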