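# Differentiable training objective: Dice + binary cross-entropy + focal
# loss on the sigmoid probability map. Dice uses soft confusion counts so
# the same formula serves training (real-valued p) and evaluation
# (thresholded p).

#' Loss configuration
#'
#' @param focal_alpha Balancing weight of the focal term (default 0.25).
#' @param focal_gamma Focusing exponent of the focal term (default 2);
#'   at 0 the focal term reduces to `alpha`-scaled cross-entropy.
#' @param smooth_eps Smoothing added to numerator and denominator of the
#'   Dice ratio so an empty ground truth with an empty prediction scores
#'   loss 0 (default 1e-6).
#' @param component_weights Numeric length-3 weights of (Dice, BCE, focal)
#'   in the combined loss; default `c(1, 1, 1)`. Zeroing entries selects
#'   single losses or pairs.
#' @param focal_literal If `TRUE`, the focal term uses `log(p)` for every
#'   pixel regardless of its label (the printed form); the default `FALSE`
#'   uses the standard `p_t` substitution so background pixels contribute.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(focal_alpha = 0.25, focal_gamma = 2.0,
                        smooth_eps = 1e-6, component_weights = c(1, 1, 1),
                        focal_literal = FALSE) {
  stopifnot(focal_gamma >= 0, smooth_eps > 0, length(component_weights) == 3)
  structure(
    list(
      focal_alpha = focal_alpha, focal_gamma = focal_gamma,
      smooth_eps = smooth_eps, component_weights = as.numeric(component_weights),
      focal_literal = isTRUE(focal_literal)
    ),
    class = "loss_config"
  )
}

check_yp <- function(y, p) {
  if (!identical(dim(y), dim(p)) || length(y) != length(p)) {
    stop("y and p must have identical shape", call. = FALSE)
  }
  if (any(y != 0 & y != 1)) stop("y must be binary (0/1)", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

BCE_CLIP <- 1e-7

#' Soft confusion counts
#'
#' Differentiable reading of the confusion tallies:
#' `tp = sum(y * p)`, `fp = sum((1 - y) * p)`, `fn = sum(y * (1 - p))`,
#' `tn = sum((1 - y) * (1 - p))`. Exact integer tallies when `p` is binary.
#'
#' @param y Binary ground-truth mask (any numeric array/vector of 0/1).
#' @param p Predicted probabilities in \[0, 1\], same shape as `y`.
#' @return List with fields `tp`, `fp`, `fn`, `tn`.
#' @export
soft_counts <- function(y, p) {
  check_yp(y, p)
  list(
    tp = sum(y * p), fp = sum((1 - y) * p),
    fn = sum(y * (1 - p)), tn = sum((1 - y) * (1 - p))
  )
}

#' Dice loss
#'
#' `1 - (2 tp + eps) / (2 tp + fp + fn + eps)` with soft counts, so a
#' perfect prediction scores 0 and a disjoint one scores 1. Empty ground
#' truth with empty prediction scores 0 under the smoothing convention.
#'
#' @inheritParams soft_counts
#' @param cfg A [loss_config()].
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(y, p, cfg = loss_config()) {
  ct <- soft_counts(y, p)
  eps <- cfg$smooth_eps
  1 - (2 * ct$tp + eps) / (2 * ct$tp + ct$fp + ct$fn + eps)
}

dice_loss_grad <- function(y, p, cfg = loss_config()) {
  ct <- soft_counts(y, p)
  eps <- cfg$smooth_eps
  num <- 2 * ct$tp + eps
  den <- 2 * ct$tp + ct$fp + ct$fn + eps
  # d(den)/dp = 1 per pixel, d(num)/dp = 2 y
  -(2 * y * den - num) / den^2
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]`, with `p` clipped
#' to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @inheritParams soft_counts
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, p) {
  check_yp(y, p)
  pc <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

bce_loss_grad <- function(y, p) {
  pc <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  (-y / pc + (1 - y) / (1 - pc)) / length(y)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha (1 - p_t)^gamma log(p_t)` with
#' `p_t = p` on foreground and `1 - p` on background. At `gamma = 0`,
#' `alpha = 1` it equals the cross-entropy loss. With
#' `cfg$focal_literal = TRUE` the label substitution is skipped and
#' `p_t = p` everywhere.
#'
#' @inheritParams dice_loss
#' @return Non-negative scalar.
#' @export
focal_loss <- function(y, p, cfg = loss_config()) {
  check_yp(y, p)
  pc <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  pt <- if (cfg$focal_literal) pc else y * pc + (1 - y) * (1 - pc)
  -mean(cfg$focal_alpha * (1 - pt)^cfg$focal_gamma * log(pt))
}

focal_loss_grad <- function(y, p, cfg = loss_config()) {
  pc <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  inside <- p > BCE_CLIP & p < 1 - BCE_CLIP
  pt <- if (cfg$focal_literal) pc else y * pc + (1 - y) * (1 - pc)
  g <- cfg$focal_gamma
  dlt <- cfg$focal_alpha *
    (g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) - (1 - pt)^g / pt) / length(y)
  dpt_dp <- if (cfg$focal_literal) 1 else 2 * y - 1
  dlt * dpt_dp * inside
}

#' Combined segmentation loss
#'
#' Weighted sum of Dice, BCE and focal losses; the default weights
#' `c(1, 1, 1)` give their plain sum.
#'
#' @inheritParams dice_loss
#' @return Scalar loss.
#' @export
combined_loss <- function(y, p, cfg = loss_config()) {
  w <- cfg$component_weights
  w[1] * dice_loss(y, p, cfg) + w[2] * bce_loss(y, p) +
    w[3] * focal_loss(y, p, cfg)
}

combined_loss_grad <- function(y, p, cfg = loss_config()) {
  w <- cfg$component_weights
  g <- 0
  if (w[1] != 0) g <- g + w[1] * dice_loss_grad(y, p, cfg)
  if (w[2] != 0) g <- g + w[2] * bce_loss_grad(y, p)
  if (w[3] != 0) g <- g + w[3] * focal_loss_grad(y, p, cfg)
  g
}

# Batch variants: Dice is computed per image and averaged (it is a
# set-overlap statistic, so pooling across images would let large lesions
# dominate); BCE and focal are already per-pixel means, so averaging their
# per-image values is identical to the pooled mean.
batch_combined_loss <- function(y4, p4, cfg = loss_config()) {
  nb <- dim(y4)[4]
  tot <- 0
  for (bi in seq_len(nb)) {
    tot <- tot + combined_loss(
      array(y4[, , , bi], dim = dim(y4)[1:3]),
      array(p4[, , , bi], dim = dim(p4)[1:3]), cfg
    )
  }
  tot / nb
}

batch_combined_loss_grad <- function(y4, p4, cfg = loss_config()) {
  nb <- dim(y4)[4]
  g <- array(0, dim = dim(y4))
  for (bi in seq_len(nb)) {
    g[, , , bi] <- combined_loss_grad(
      array(y4[, , , bi], dim = dim(y4)[1:3]),
      array(p4[, , , bi], dim = dim(p4)[1:3]), cfg
    ) / nb
  }
  g
}
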