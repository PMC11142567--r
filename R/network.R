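# Residual U-Net assembly. Encoder stages are residual blocks separated by
# 2x2 stride-2 downsampling convolutions; the bottleneck is a residual
# block optionally followed by the SWA block; decoder stages upsample with
# 2x2 transposed convolutions, concatenate the attention-gated skip and
# refine with a residual block; a 1x1 convolution plus sigmoid emits the
# per-pixel foreground probability.

#' Architecture configuration
#'
#' @param depth Number of encoder stages (default 4). The input spatial
#'   dims must be divisible by `2^depth`.
#' @param base_filters Channels of the first stage (default 32); widths
#'   double per stage and the bottleneck holds `base_filters * 2^depth`.
#' @param attention_mode Skip-connection gating: `"none"`, `"pam"`,
#'   `"cbam"` or `"pcbam"`. Together with `use_swa` this selects the five
#'   ablation variants: (`none`, no SWA) is the plain residual U-Net;
#'   (`pam`)/(`cbam`)/(`pcbam`) without SWA add one attention family each;
#'   (`pcbam`, SWA) is the full model.
#' @param use_swa Insert the bottleneck attention block. Default `FALSE`.
#' @param swa_placement `"bottleneck"` (default) applies SWA between the
#'   deepest encoder feature and the first decoder stage; `"decoder"`
#'   applies it after the deepest decoder residual block instead.
#' @param input_size Integer vector `c(H, W, C)`; default `c(128, 128, 1)`.
#' @param reduction Channel-MLP reduction ratio inside CBAM (default 8).
#' @param sam_dense Keep the per-position dense layers inside spatial
#'   attention (default `TRUE`).
#' @param skip_fusion `"concat"` (default) concatenates gated skip and
#'   upsampled features before the decoder residual block; `"add"` sums
#'   them instead.
#' @param seed Seed for He-normal weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(depth = 4L, base_filters = 32L,
                         attention_mode = c("none", "pam", "cbam", "pcbam"),
                         use_swa = FALSE,
                         swa_placement = c("bottleneck", "decoder"),
                         input_size = c(128L, 128L, 1L),
                         reduction = 8L, sam_dense = TRUE,
                         skip_fusion = c("concat", "add"),
                         seed = 1L) {
  attention_mode <- match.arg(attention_mode)
  swa_placement <- match.arg(swa_placement)
  skip_fusion <- match.arg(skip_fusion)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  input_size <- as.integer(input_size)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (base_filters < 1L) stop("base_filters must be >= 1", call. = FALSE)
  if (length(input_size) != 3L) stop("input_size must be c(H, W, C)", call. = FALSE)
  if (any(input_size[1:2] %% 2L^depth != 0L)) {
    stop("input spatial dims must be divisible by 2^depth", call. = FALSE)
  }
  structure(
    list(
      depth = depth, base_filters = base_filters,
      attention_mode = attention_mode, use_swa = isTRUE(use_swa),
      swa_placement = swa_placement, input_size = input_size,
      reduction = as.integer(reduction), sam_dense = isTRUE(sam_dense),
      skip_fusion = skip_fusion, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

stage_filters <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)

# Convolutions immediately followed by batch normalization carry no bias
# (BN's beta would absorb it and its gradient is exactly zero through
# batch statistics).
conv_params <- function(kh, kw, cin, cout, seed, bias = TRUE) {
  p <- with_seed(
    seed,
    list(w = he_init(c(kh, kw, cin, cout), kh * kw * cin))
  )
  if (bias) p$b <- numeric(cout)
  p
}

conv_bias <- function(p, cout) if (is.null(p[["b"]])) numeric(cout) else p[["b"]]

res_block_params <- function(cin, cout, seed) {
  p <- list(
    conv1 = conv_params(3L, 3L, cin, cout, derive_seed(seed, 1L), bias = FALSE),
    bn1 = bn_params(cout),
    conv2 = conv_params(3L, 3L, cout, cout, derive_seed(seed, 2L), bias = FALSE),
    bn2 = bn_params(cout)
  )
  if (cin != cout) {
    p$proj <- conv_params(1L, 1L, cin, cout, derive_seed(seed, 3L))
  }
  p
}

res_block_state <- function(cout) list(bn1 = bn_state(cout), bn2 = bn_state(cout))

#' Build a segmentation model
#'
#' Instantiates all parameters (He-normal, reproducible under `cfg$seed`)
#' and the batch-normalization running statistics for the configured
#' architecture.
#'
#' @param cfg A [model_config()].
#' @return Object of class `segmodel` with elements `config`, `params` and
#'   `state`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  filt <- stage_filters(cfg)
  cb <- cfg$base_filters * 2L^cfg$depth # bottleneck width
  params <- list(enc = list(), down = list(), dec = list(), att = list())
  state <- list(enc = list(), down = list(), dec = list())
  cin <- cfg$input_size[3]
  for (s in seq_len(cfg$depth)) {
    params$enc[[s]] <- res_block_params(cin, filt[s], derive_seed(cfg$seed, 10L + s))
    state$enc[[s]] <- res_block_state(filt[s])
    cnext <- if (s < cfg$depth) filt[s + 1L] else cb
    params$down[[s]] <- c(
      conv_params(2L, 2L, filt[s], cnext, derive_seed(cfg$seed, 30L + s),
        bias = FALSE
      ),
      list(bn = bn_params(cnext))
    )
    state$down[[s]] <- list(bn = bn_state(cnext))
    cin <- cnext
  }
  params$bottleneck <- res_block_params(cb, cb, derive_seed(cfg$seed, 50L))
  state$bottleneck <- res_block_state(cb)
  if (cfg$use_swa) {
    swa_ch <- if (cfg$swa_placement == "bottleneck") cb else filt[cfg$depth]
    params$swa <- swa_params(swa_ch, seed = derive_seed(cfg$seed, 60L))
  }
  for (s in seq_len(cfg$depth)) {
    if (cfg$attention_mode == "pcbam") {
      params$att[[s]] <- pcbam_params(filt[s],
        reduction = cfg$reduction,
        sam_dense = cfg$sam_dense,
        seed = derive_seed(cfg$seed, 70L + s)
      )
    } else if (cfg$attention_mode == "cbam") {
      params$att[[s]] <- pcbam_params(filt[s],
        reduction = cfg$reduction,
        sam_dense = cfg$sam_dense,
        seed = derive_seed(cfg$seed, 70L + s)
      )[c("cam", "sam")]
    } else if (cfg$attention_mode == "pam") {
      params$att[[s]] <- list(pam = pam_params(filt[s],
        init = "he",
        seed = derive_seed(cfg$seed, 70L + s)
      ))
    }
  }
  for (s in rev(seq_len(cfg$depth))) {
    cprev <- if (s == cfg$depth) cb else filt[s + 1L]
    merged_in <- if (cfg$skip_fusion == "concat") 2L * filt[s] else filt[s]
    params$dec[[s]] <- list(
      up = c(
        conv_params(2L, 2L, cprev, filt[s], derive_seed(cfg$seed, 90L + s),
          bias = FALSE
        ),
        list(bn = bn_params(filt[s]))
      ),
      res = res_block_params(merged_in, filt[s], derive_seed(cfg$seed, 110L + s))
    )
    state$dec[[s]] <- list(
      up = list(bn = bn_state(filt[s])),
      res = res_block_state(filt[s])
    )
  }
  params$head <- conv_params(1L, 1L, filt[1], 1L, derive_seed(cfg$seed, 130L))
  structure(list(config = cfg, params = params, state = state),
    class = "segmodel"
  )
}

#' Number of trainable parameters
#'
#' @param model A `segmodel`.
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(model) as.integer(tree_count(model$params))

# ---- residual block ---------------------------------------------------------

res_block_forward <- function(x, p, st, training, cache = FALSE,
                              momentum = 0.9) {
  c1 <- conv2d_forward(x, p$conv1$w, conv_bias(p$conv1, dim(p$conv1$w)[4]),
    cache = cache
  )
  b1 <- bn_forward(c1$out, p$bn1, st$bn1, training,
    momentum = momentum, cache = cache
  )
  r1 <- relu_forward(b1$out)
  c2 <- conv2d_forward(r1$out, p$conv2$w, conv_bias(p$conv2, dim(p$conv2$w)[4]),
    cache = cache
  )
  b2 <- bn_forward(c2$out, p$bn2, st$bn2, training,
    momentum = momentum, cache = cache
  )
  r2 <- relu_forward(b2$out)
  if (is.null(p$proj)) {
    short <- x
    pc <- NULL
  } else {
    pc <- conv2d_forward(x, p$proj$w, p$proj$b, cache = cache)
    short <- pc$out
  }
  st$bn1 <- b1$state
  st$bn2 <- b2$state
  list(
    out = r2$out + short, state = st,
    cache = if (cache) {
      list(
        c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
        c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
        proj = if (!is.null(pc)) pc$cache, has_proj = !is.null(p$proj)
      )
    }
  )
}

res_block_backward <- function(p, cache, dout) {
  dr2 <- relu_backward(cache$r2, dout)
  b2 <- bn_backward(cache$b2, dr2)
  c2 <- conv2d_backward(cache$c2, b2$dx)
  dr1 <- relu_backward(cache$r1, c2$dx)
  b1 <- bn_backward(cache$b1, dr1)
  c1 <- conv2d_backward(cache$c1, b1$dx)
  grads <- list(
    conv1 = list(w = c1$dw),
    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
    conv2 = list(w = c2$dw),
    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta)
  )
  if (cache$has_proj) {
    pj <- conv2d_backward(cache$proj, dout)
    grads$proj <- list(w = pj$dw, b = pj$db)
    dx <- c1$dx + pj$dx
  } else {
    dx <- c1$dx + dout
  }
  list(dx = dx, grads = grads)
}

# ---- attention over a batch -------------------------------------------------

att_forward_batch <- function(x, mode, p, cache = FALSE) {
  if (mode == "none") {
    return(list(out = x, cache = NULL))
  }
  d <- dim(x)
  out <- array(0, dim = d)
  caches <- if (cache) vector("list", d[4]) else NULL
  for (bi in seq_len(d[4])) {
    f <- array(x[, , , bi], dim = d[1:3])
    r <- switch(mode,
      pam = pam_forward(f, p$pam, cache = cache),
      cbam = cbam_forward(f, p, cache = cache),
      pcbam = pcbam_forward(f, p, cache = cache)
    )
    out[, , , bi] <- r$out
    if (cache) caches[[bi]] <- r$cache
  }
  list(out = out, cache = caches)
}

att_backward_batch <- function(x_dims, mode, p, caches, dout) {
  dx <- array(0, dim = x_dims)
  grads <- NULL
  for (bi in seq_len(x_dims[4])) {
    dge <- array(dout[, , , bi], dim = x_dims[1:3])
    r <- switch(mode,
      pam = {
        z <- pam_backward(p$pam, caches[[bi]], dge)
        list(df = z$df, grads = list(pam = z$grads))
      },
      cbam = cbam_backward(p, caches[[bi]], dge),
      pcbam = pcbam_backward(p, caches[[bi]], dge)
    )
    dx[, , , bi] <- r$df
    grads <- if (is.null(grads)) r$grads else tree_map2(`+`, grads, r$grads)
  }
  list(dx = dx, grads = grads)
}

swa_forward_batch <- function(x, p, cache = FALSE) {
  d <- dim(x)
  out <- array(0, dim = d)
  caches <- if (cache) vector("list", d[4]) else NULL
  for (bi in seq_len(d[4])) {
    r <- swa_forward(array(x[, , , bi], dim = d[1:3]), p, cache = cache)
    out[, , , bi] <- r$out
    if (cache) caches[[bi]] <- r$cache
  }
  list(out = out, cache = caches)
}

swa_backward_batch <- function(x_dims, p, caches, dout) {
  dx <- array(0, dim = x_dims)
  grads <- NULL
  for (bi in seq_len(x_dims[4])) {
    r <- swa_backward(p, caches[[bi]], array(dout[, , , bi], dim = x_dims[1:3]))
    dx[, , , bi] <- r$df
    grads <- if (is.null(grads)) r$grads else tree_map2(`+`, grads, r$grads)
  }
  list(dx = dx, grads = grads)
}

# ---- full forward / backward ------------------------------------------------

check_input_batch <- function(model, x) {
  x <- as_batch(x)
  isz <- model$config$input_size
  if (!identical(dim(x)[1:3], isz)) {
    stop("input must be ", paste(isz, collapse = " x "),
      " (got ", paste(dim(x)[1:3], collapse = " x "), ")",
      call. = FALSE
    )
  }
  if (!all(is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  x
}

seg_forward <- function(model, x, training = FALSE, cache = FALSE,
                        taps = FALSE, momentum = 0.9) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  x <- check_input_batch(model, x)
  cc <- list()
  tp <- list()
  enc_out <- vector("list", cfg$depth)
  cur <- x
  for (s in seq_len(cfg$depth)) {
    rb <- res_block_forward(cur, p$enc[[s]], st$enc[[s]], training, cache,
      momentum = momentum
    )
    st$enc[[s]] <- rb$state
    enc_out[[s]] <- rb$out
    cc[[paste0("enc", s)]] <- rb$cache
    dn <- conv2d_forward(rb$out, p$down[[s]]$w,
      conv_bias(p$down[[s]], dim(p$down[[s]]$w)[4]),
      stride = 2L, padding = "valid", cache = cache
    )
    bnr <- bn_forward(dn$out, p$down[[s]]$bn, st$down[[s]]$bn, training,
      momentum = momentum, cache = cache
    )
    st$down[[s]]$bn <- bnr$state
    rl <- relu_forward(bnr$out)
    cc[[paste0("down", s)]] <- list(conv = dn$cache, bn = bnr$cache, relu = rl$cache)
    cur <- rl$out
  }
  bt <- res_block_forward(cur, p$bottleneck, st$bottleneck, training, cache,
    momentum = momentum
  )
  st$bottleneck <- bt$state
  cc$bottleneck <- bt$cache
  cur <- bt$out
  if (cfg$use_swa && cfg$swa_placement == "bottleneck") {
    sw <- swa_forward_batch(cur, p$swa, cache)
    cc$swa <- sw$cache
    cc$swa_in_dims <- dim(cur)
    cur <- sw$out
    if (taps) tp$swa <- cur
  }
  if (taps) tp$F_c <- cur
  for (s in rev(seq_len(cfg$depth))) {
    up <- convtranspose2_forward(
      cur, p$dec[[s]]$up$w,
      conv_bias(p$dec[[s]]$up, dim(p$dec[[s]]$up$w)[4]), cache
    )
    ub <- bn_forward(up$out, p$dec[[s]]$up$bn, st$dec[[s]]$up$bn, training,
      momentum = momentum, cache = cache
    )
    st$dec[[s]]$up$bn <- ub$state
    ur <- relu_forward(ub$out)
    cc[[paste0("up", s)]] <- list(ct = up$cache, bn = ub$cache, relu = ur$cache)
    at <- att_forward_batch(enc_out[[s]], cfg$attention_mode, p$att[[s]], cache)
    cc[[paste0("att", s)]] <- at$cache
    cc[[paste0("att", s, "_dims")]] <- dim(enc_out[[s]])
    if (taps && cfg$attention_mode != "none") {
      tp[[paste0("attention", s)]] <- at$out
    }
    merged <- if (cfg$skip_fusion == "concat") {
      abind4(ur$out, at$out)
    } else {
      ur$out + at$out
    }
    rb <- res_block_forward(merged, p$dec[[s]]$res, st$dec[[s]]$res, training,
      cache,
      momentum = momentum
    )
    st$dec[[s]]$res <- rb$state
    cc[[paste0("dec", s)]] <- rb$cache
    cur <- rb$out
    if (cfg$use_swa && cfg$swa_placement == "decoder" && s == cfg$depth) {
      sw <- swa_forward_batch(cur, p$swa, cache)
      cc$swa <- sw$cache
      cc$swa_in_dims <- dim(cur)
      cur <- sw$out
      if (taps) tp$swa <- cur
    }
  }
  hd <- conv2d_forward(cur, p$head$w, p$head$b, cache = cache)
  sg <- sigmoid_forward(hd$out)
  cc$head <- hd$cache
  cc$head_sig <- sg$cache
  if (taps) {
    tp$F_a <- enc_out[[1L]]
    if (cfg$depth >= 2L) tp$F_b <- enc_out[[2L]]
  }
  list(
    out = sg$out, state = st,
    cache = if (cache) cc,
    taps = if (taps) tp
  )
}

# Concatenate two batches along the channel axis.
abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Gradient of the full network given d(loss)/d(probability map). Returns a
# tree shaped like model$params.
seg_backward <- function(model, cc, dprob) {
  cfg <- model$config
  p <- model$params
  g <- list(enc = list(), down = list(), dec = list(), att = list())
  dcur <- sigmoid_backward(cc$head_sig, dprob)
  hd <- conv2d_backward(cc$head, dcur)
  g$head <- list(w = hd$dw, b = hd$db)
  dcur <- hd$dx
  denc <- vector("list", cfg$depth)
  for (s in seq_len(cfg$depth)) {
    if (cfg$use_swa && cfg$swa_placement == "decoder" && s == cfg$depth) {
      sw <- swa_backward_batch(cc$swa_in_dims, p$swa, cc$swa, dcur)
      g$swa <- sw$grads
      dcur <- sw$dx
    }
    rb <- res_block_backward(p$dec[[s]]$res, cc[[paste0("dec", s)]], dcur)
    g$dec[[s]] <- list(res = rb$grads)
    dmerged <- rb$dx
    nf <- stage_filters(cfg)[s]
    if (cfg$skip_fusion == "concat") {
      dup <- dmerged[, , seq_len(nf), , drop = FALSE]
      datt <- dmerged[, , nf + seq_len(nf), , drop = FALSE]
    } else {
      dup <- dmerged
      datt <- dmerged
    }
    if (cfg$attention_mode != "none") {
      ab <- att_backward_batch(
        cc[[paste0("att", s, "_dims")]], cfg$attention_mode,
        p$att[[s]], cc[[paste0("att", s)]], datt
      )
      g$att[[s]] <- ab$grads
      denc[[s]] <- ab$dx
    } else {
      denc[[s]] <- datt
    }
    upc <- cc[[paste0("up", s)]]
    dur <- relu_backward(upc$relu, dup)
    ub <- bn_backward(upc$bn, dur)
    ct <- convtranspose2_backward(upc$ct, ub$dx)
    g$dec[[s]]$up <- list(
      w = ct$dw,
      bn = list(gamma = ub$dgamma, beta = ub$dbeta)
    )
    dcur <- ct$dx
  }
  if (cfg$use_swa && cfg$swa_placement == "bottleneck") {
    sw <- swa_backward_batch(cc$swa_in_dims, p$swa, cc$swa, dcur)
    g$swa <- sw$grads
    dcur <- sw$dx
  }
  bt <- res_block_backward(p$bottleneck, cc$bottleneck, dcur)
  g$bottleneck <- bt$grads
  dcur <- bt$dx
  for (s in rev(seq_len(cfg$depth))) {
    dnc <- cc[[paste0("down", s)]]
    drl <- relu_backward(dnc$relu, dcur)
    db <- bn_backward(dnc$bn, drl)
    cv <- conv2d_backward(dnc$conv, db$dx)
    g$down[[s]] <- list(
      w = cv$dw,
      bn = list(gamma = db$dgamma, beta = db$dbeta)
    )
    dtotal <- cv$dx + denc[[s]]
    rb <- res_block_backward(p$enc[[s]], cc[[paste0("enc", s)]], dtotal)
    g$enc[[s]] <- rb$grads
    dcur <- rb$dx
  }
  g
}

#' Re-estimate batch-normalization running statistics
#'
#' Replaces the exponentially smoothed running moments with the exact
#' population moments of every normalized activation over `pairs`, under
#' the model's current (frozen) weights. With few, short training runs the
#' smoothed estimates lag far behind the statistics the network was
#' actually normalized with, which degrades inference-mode predictions;
#' re-estimation removes that lag.
#'
#' @param model A `segmodel`.
#' @param pairs List of image/mask pairs (typically the training set).
#' @param batch_size Images per forward pass, default 8.
#' @return The model with updated `state`.
#' @export
recalibrate_bn <- function(model, pairs, batch_size = 8L) {
  n <- length(pairs)
  stopifnot(n >= 1L)
  acc <- NULL # per-leaf: list(mean, sq) accumulated over batches
  wts <- numeric()
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + as.integer(batch_size) - 1L)
    x4 <- stack_images(pairs[i0:i1])
    # momentum 0 makes each returned state carry that batch's exact stats
    st <- seg_forward(model, x4, training = TRUE, momentum = 0)$state
    wts <- c(wts, i1 - i0 + 1L)
    acc <- c(acc, list(st))
    i0 <- i1 + 1L
  }
  wts <- wts / sum(wts)
  model$state <- merge_bn_states(acc, wts)
  model
}

# Pool per-batch BN states: pooled mean is the weighted mean; pooled
# variance is E[x^2] - E[x]^2 with E[x^2] recovered from var + mean^2.
merge_bn_states <- function(states, wts) {
  walk <- function(parts) {
    first <- parts[[1]]
    if (is.list(first) && !is.null(first$mean) && !is.null(first$var)) {
      mu <- 0
      m2 <- 0
      for (k in seq_along(parts)) {
        mu <- mu + wts[k] * parts[[k]]$mean
        m2 <- m2 + wts[k] * (parts[[k]]$var + parts[[k]]$mean^2)
      }
      return(list(mean = mu, var = pmax(m2 - mu^2, 0)))
    }
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (j in seq_along(first)) {
      out[[j]] <- walk(lapply(parts, `[[`, j))
    }
    out
  }
  walk(states)
}

# Reorder a gradient tree to the exact layout of model$params so the
# optimizer can walk both trees in lock-step.
align_grads <- function(params, grads) {
  if (!is.list(params)) {
    if (!is.numeric(params)) return(params) # structure flags, not weights
    if (is.null(grads)) stop("missing gradient leaf", call. = FALSE)
    return(grads)
  }
  out <- vector("list", length(params))
  names(out) <- names(params)
  idx <- names(params)
  if (is.null(idx)) idx <- seq_along(params)
  for (k in seq_along(params)) {
    key <- if (is.character(idx)) idx[k] else k
    out[[k]] <- align_grads(params[[k]], grads[[key]])
  }
  out
}

#' Forward pass returning the prediction and named intermediate activations
#'
#' Runs the model in inference mode on one image and returns the
#' probability map together with the taps used for heatmap export: `F_a`
#' and `F_b` (first and second encoder-stage features feeding the skip
#' connections), `F_c` (bottleneck feature, after SWA when present),
#' per-skip attention outputs (`attention1`, `attention2`, ...) and `swa`.
#'
#' @param model A `segmodel`.
#' @param image Array `H x W x 1` (or `H x W` matrix) matching the
#'   configured input size, values in \[0, 1\].
#' @return List with `prob` (`H x W x 1` probability grid) and `taps`
#'   (named list of feature batches).
#' @export
forward_with_taps <- function(model, image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  r <- seg_forward(model, image, training = FALSE, taps = TRUE)
  prob <- array(r$out, dim = dim(r$out)[1:3])
  list(prob = prob, taps = r$taps)
}

#' Predict probability maps
#'
#' @param object A `segmodel`.
#' @param newdata Array `H x W x 1`, `H x W x 1 x B` batch, or a list of
#'   image/mask pairs (the `image` element of each is used).
#' @param ... Unused.
#' @return Array `H x W x 1 x B` of foreground probabilities in (0, 1).
#' @export
predict.segmodel <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.array(newdata)) {
    newdata <- stack_images(newdata)
  }
  seg_forward(object, newdata, training = FALSE)$out
}

stack_images <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  out <- array(0, dim = c(d, length(pairs)))
  for (i in seq_along(pairs)) out[, , , i] <- pairs[[i]]$image
  out
}

stack_masks <- function(pairs) {
  d <- dim(pairs[[1]]$mask)
  out <- array(0, dim = c(d, length(pairs)))
  for (i in seq_along(pairs)) out[, , , i] <- pairs[[i]]$mask
  out
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' Writes a single-file archive holding the format version, the full
#' architecture configuration, every parameter tensor and the
#' batch-normalization running statistics.
#'
#' @param model A `segmodel`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "segmodel"))
  saveRDS(
    list(
      version = CHECKPOINT_VERSION,
      config = unclass(model$config),
      params = model$params,
      state = model$state
    ),
    path
  )
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `segmodel`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != CHECKPOINT_VERSION) {
    stop("unsupported checkpoint version: ",
      if (is.null(ck$version)) "<missing>" else ck$version,
      " (expected ", CHECKPOINT_VERSION, ")",
      call. = FALSE
    )
  }
  cfg <- do.call(model_config, ck$config[setdiff(
    names(ck$config),
    character()
  )])
  structure(list(config = cfg, params = ck$params, state = ck$state),
    class = "segmodel"
  )
}
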