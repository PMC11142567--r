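# Independent straight-line oracles. Everything here is written as naive
# nested loops over the defining formulas, deliberately sharing no code
# with the package's vectorized/compiled implementations.

rel_err <- function(a, b) {
  scale <- max(abs(b), 1e-8)
  max(abs(a - b)) / scale
}

rand_grid <- function(h, w, ch, sd = 1) {
  array(stats::rnorm(h * w * ch, sd = sd), dim = c(h, w, ch))
}

o_sigmoid <- function(x) 1 / (1 + exp(-x))

# Plain 2-d convolution with "same" zero padding, arbitrary dilation,
# stride 1. x: H x W x Cin array, w: kh x kw x Cin x Cout, b: length Cout.
o_conv2d_same <- function(x, w, b, dilation = 1L) {
  d <- dim(x)
  kd <- dim(w)
  ph <- dilation * (kd[1] - 1L) %/% 2L
  pw <- dilation * (kd[2] - 1L) %/% 2L
  out <- array(0, dim = c(d[1], d[2], kd[4]))
  for (co in seq_len(kd[4])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- b[co]
        for (ki in seq_len(kd[1])) {
          for (kj in seq_len(kd[2])) {
            ii <- i + (ki - 1L) * dilation - ph
            jj <- j + (kj - 1L) * dilation - pw
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
              for (ci in seq_len(kd[3])) {
                acc <- acc + x[ii, jj, ci] * w[ki, kj, ci, co]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

# Channel attention: sigmoid(mlp(gap) + mlp(gmp)), shared two-layer MLP
# with a ReLU after the bottleneck layer.
o_channel_gate <- function(f, p) {
  d <- dim(f)
  gap <- numeric(d[3])
  gmp <- numeric(d[3])
  for (c in seq_len(d[3])) {
    gap[c] <- mean(f[, , c])
    gmp[c] <- max(f[, , c])
  }
  mlp <- function(v) {
    h <- numeric(ncol(p$w1))
    for (k in seq_len(ncol(p$w1))) {
      h[k] <- max(0, sum(v * p$w1[, k]) + p$b1[k])
    }
    out <- numeric(ncol(p$w2))
    for (c in seq_len(ncol(p$w2))) {
      out[c] <- sum(h * p$w2[, c]) + p$b2[c]
    }
    out
  }
  o_sigmoid(mlp(gap) + mlp(gmp))
}

# Spatial attention: channel-wise average and max maps, optional scalar
# dense layers, 7x7 dilated convolution, sigmoid.
o_spatial_gate <- function(fcp, p) {
  d <- dim(fcp)
  avg <- matrix(0, d[1], d[2])
  mx <- matrix(-Inf, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      avg[i, j] <- mean(fcp[i, j, ])
      mx[i, j] <- max(fcp[i, j, ])
    }
  }
  if (p$dense) {
    avg <- p$wa * avg + p$ba
    mx <- p$wm * mx + p$bm
  }
  pooled <- array(0, dim = c(d[1], d[2], 2L))
  pooled[, , 1] <- avg
  pooled[, , 2] <- mx
  conv <- o_conv2d_same(pooled, p$conv_w, p$conv_b, dilation = 4L)
  array(o_sigmoid(conv), dim = c(d[1], d[2], 1L))
}

o_cbam <- function(f, p) {
  d <- dim(f)
  g <- o_channel_gate(f, p$cam)
  fcp <- f
  for (c in seq_len(d[3])) fcp[, , c] <- f[, , c] * g[c]
  sp <- o_spatial_gate(fcp, p$sam)
  out <- fcp
  for (c in seq_len(d[3])) out[, , c] <- fcp[, , c] * sp[, , 1]
  out
}

# Position attention by explicit O(N^2 C) double loops. Position index
# follows column-major (row-fastest) flattening of the H x W plane.
o_pam_project <- function(f, w, b) {
  d <- dim(f)
  n <- d[1] * d[2]
  out <- matrix(0, n, ncol(w))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      pos <- i + d[1] * (j - 1L)
      for (k in seq_len(ncol(w))) {
        out[pos, k] <- sum(f[i, j, ] * w[, k]) + b[k]
      }
    }
  }
  out
}

o_position_affinity <- function(f, p) {
  bm <- o_pam_project(f, p$wb, p$bb)
  zm <- o_pam_project(f, p$wz, p$bz)
  n <- nrow(bm)
  s <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    for (i in seq_len(n)) e[i] <- exp(sum(bm[i, ] * zm[j, ]))
    s[j, ] <- e / sum(e)
  }
  s
}

o_position_attention <- function(f, p) {
  d <- dim(f)
  s <- o_position_affinity(f, p)
  dm <- o_pam_project(f, p$wd, p$bd)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      pos <- i + d[1] * (j - 1L)
      att <- numeric(d[3])
      for (ii in seq_len(nrow(dm))) att <- att + s[pos, ii] * dm[ii, ]
      out[i, j, ] <- p$alpha * att + f[i, j, ]
    }
  }
  out
}

o_pcbam <- function(f, p) o_position_attention(f, p$pam) + o_cbam(f, p)

# Bottleneck attention: per-pixel q/k/v projections, 1x1 fusion of the
# concatenation, residual add.
o_swa <- function(f, p) {
  d <- dim(f)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- f[i, j, ]
      q <- as.numeric(v %*% p$wq)
      k <- as.numeric(v %*% p$wk)
      vv <- as.numeric(v %*% p$wv)
      a <- as.numeric(c(q, k, vv) %*% p$wf) + p$bf
      out[i, j, ] <- v + a
    }
  }
  out
}

# Element-wise loop versions of the losses.
o_soft_counts <- function(y, p) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y)) {
    tp <- tp + y[i] * p[i]
    fp <- fp + (1 - y[i]) * p[i]
    fn <- fn + y[i] * (1 - p[i])
    tn <- tn + (1 - y[i]) * (1 - p[i])
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

o_bce <- function(y, p) {
  tot <- 0
  for (i in seq_along(y)) {
    pc <- min(max(p[i], 1e-7), 1 - 1e-7)
    tot <- tot - (y[i] * log(pc) + (1 - y[i]) * log(1 - pc))
  }
  tot / length(y)
}

o_focal <- function(y, p, alpha = 0.25, gamma = 2) {
  tot <- 0
  for (i in seq_along(y)) {
    pc <- min(max(p[i], 1e-7), 1 - 1e-7)
    pt <- if (y[i] == 1) pc else 1 - pc
    tot <- tot - alpha * (1 - pt)^gamma * log(pt)
  }
  tot / length(y)
}

o_confusion <- function(y, yhat) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && yhat[i] == 1) tp <- tp + 1
    if (y[i] == 0 && yhat[i] == 1) fp <- fp + 1
    if (y[i] == 1 && yhat[i] == 0) fn <- fn + 1
    if (y[i] == 0 && yhat[i] == 0) tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
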