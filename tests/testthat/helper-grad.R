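# Central-difference gradient helpers used by the differentiability tests.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Flatten/unflatten helpers mirroring the package's parameter-tree layout
# (walk order is list order, leaves in column-major order).
flatten_params <- function(p) ultraseg:::tree_flatten(p)

set_params_from <- function(params, flat) {
  i <- 1
  ultraseg:::tree_map(function(a) {
    n <- length(a)
    a[] <- flat[i:(i + n - 1)]
    i <<- i + n
    a
  }, params)
}

# TRUE per parameter tensor when any entry of its gradient is nonzero.
tensor_alive <- function(grads) {
  out <- logical()
  walk <- function(a, pre) {
    if (is.list(a)) {
      nms <- names(a)
      if (is.null(nms)) nms <- seq_along(a)
      for (k in seq_along(a)) walk(a[[k]], paste0(pre, ".", nms[k]))
    } else if (is.numeric(a)) {
      out[[pre]] <<- any(a != 0)
    }
  }
  walk(grads, "p")
  out
}

make_pairs <- function(n, size = 32L, seed = 1L) {
  # small random image/mask pairs for fast training-path tests
  with_seed(seed, lapply(seq_len(n), function(i) {
    cx <- stats::runif(1, 0.3, 0.7) * size
    cy <- stats::runif(1, 0.3, 0.7) * size
    r <- stats::runif(1, 0.15, 0.3) * size
    gx <- matrix(rep(seq_len(size), size), size, size)
    gy <- matrix(rep(seq_len(size), each = size), size, size)
    mask <- ((gx - cx)^2 + (gy - cy)^2 <= r^2) * 1
    img <- 0.6 - 0.3 * mask + matrix(stats::rnorm(size^2, 0, 0.05), size, size)
    img <- pmin(pmax(img, 0), 1)
    list(
      image = array(img, dim = c(size, size, 1L)),
      mask = array(mask, dim = c(size, size, 1L)),
      id = sprintf("toy_%03d", i), class_label = "synthetic"
    )
  }))
}
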