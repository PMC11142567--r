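# Bottleneck attention block: per-position query/key/value projections
# fused by a 1x1 convolution and added back residually. The formulation is
# purely projection-based: no window partitioning and no softmax(q k^T),
# which also makes its cost linear in the number of pixels.

#' Create parameters for the bottleneck attention block
#'
#' @param channels Channel count `C` of the feature grid the block
#'   transforms.
#' @param init `"he"` for He-normal initialization or `"zero"` for all-zero
#'   parameters (with which the block is exactly the identity).
#' @param seed Integer seed used when `init = "he"`.
#' @return List with projection matrices `wq`, `wk`, `wv` (each `C x C`),
#'   the fusion kernel `wf` (`3C x C`) and fusion bias `bf`.
#' @export
swa_params <- function(channels, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  if (init == "zero") {
    list(
      wq = array(0, c(channels, channels)),
      wk = array(0, c(channels, channels)),
      wv = array(0, c(channels, channels)),
      wf = array(0, c(3L * channels, channels)),
      bf = numeric(channels)
    )
  } else {
    with_seed(seed, list(
      wq = he_init(c(channels, channels), channels),
      wk = he_init(c(channels, channels), channels),
      wv = he_init(c(channels, channels), channels),
      wf = he_init(c(3L * channels, channels), 3L * channels),
      bf = numeric(channels)
    ))
  }
}

check_swa_channels <- function(f, params) {
  if (dim(f)[3] != nrow(params$wq)) {
    stop("swa: grid has ", dim(f)[3], " channels but params expect ",
      nrow(params$wq),
      call. = FALSE
    )
  }
}

#' Query/key/value projections of the bottleneck attention block
#'
#' Applies the same linear map `C -> C` at every spatial position, once per
#' projection matrix.
#'
#' @param f Feature grid `H x W x C`.
#' @param params Parameters from [swa_params()].
#' @return List of grids `q`, `k`, `v`, each `H x W x C`.
#' @export
swa_project <- function(f, params) {
  f <- as_grid(f)
  check_swa_channels(f, params)
  d <- dim(f)
  fm <- grid_as_mat(f)
  list(
    q = array(fm %*% params$wq, dim = d),
    k = array(fm %*% params$wk, dim = d),
    v = array(fm %*% params$wv, dim = d)
  )
}

#' Fused attention map of the bottleneck attention block
#'
#' Concatenates the three projections along channels and applies the 1x1
#' fusion convolution (`3C -> C`).
#'
#' @param q,k,v Grids of identical shape `H x W x C`.
#' @param params Parameters from [swa_params()].
#' @return Attention map grid `H x W x C`.
#' @export
swa_attention_map <- function(q, k, v, params) {
  q <- as_grid(q)
  k <- as_grid(k)
  v <- as_grid(v)
  if (!identical(dim(q), dim(k)) || !identical(dim(q), dim(v))) {
    stop("swa_attention_map: q, k, v must share one shape", call. = FALSE)
  }
  d <- dim(q)
  qkv <- cbind(grid_as_mat(q), grid_as_mat(k), grid_as_mat(v))
  array(qkv %*% params$wf + rep(params$bf, each = nrow(qkv)), dim = d)
}

#' Bottleneck attention block (residual)
#'
#' `swa(f) = f + A(f)` where `A` is the fused projection map of
#' [swa_attention_map()]. With a zero fusion kernel and bias the block is
#' exactly the identity.
#'
#' @param f Feature grid `H x W x C`.
#' @param params Parameters from [swa_params()].
#' @return Grid of the same shape as `f`.
#' @export
swa <- function(f, params) {
  f <- as_grid(f)
  check_swa_channels(f, params)
  swa_forward(f, params)$out
}

swa_forward <- function(f, p, cache = FALSE) {
  d <- dim(f)
  fm <- grid_as_mat(f)
  qkv <- cbind(fm %*% p$wq, fm %*% p$wk, fm %*% p$wv)
  am <- qkv %*% p$wf + rep(p$bf, each = nrow(qkv))
  list(
    out = array(fm + am, dim = d),
    cache = if (cache) list(fm = fm, qkv = qkv, dims = d)
  )
}

swa_backward <- function(p, cache, dout) {
  d <- cache$dims
  ch <- d[3]
  da <- matrix(dout, nrow(cache$fm), ch)
  dwf <- crossprod(cache$qkv, da)
  dbf <- colSums(da)
  dqkv <- da %*% t(p$wf)
  dq <- dqkv[, seq_len(ch), drop = FALSE]
  dk <- dqkv[, ch + seq_len(ch), drop = FALSE]
  dv <- dqkv[, 2L * ch + seq_len(ch), drop = FALSE]
  dfm <- da + dq %*% t(p$wq) + dk %*% t(p$wk) + dv %*% t(p$wv)
  list(
    df = array(dfm, dim = d),
    grads = list(
      wq = crossprod(cache$fm, dq),
      wk = crossprod(cache$fm, dk),
      wv = crossprod(cache$fm, dv),
      wf = dwf, bf = dbf
    )
  )
}
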