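# Residual U-Net assembly: blocks, variants, checkpoints, gradients.

toy_cfg <- function(mode = "pcbam", swa = TRUE, size = 32L, depth = 2L,
                    base = 4L, seed = 9L, ...) {
  model_config(
    depth = depth, base_filters = base, attention_mode = mode,
    use_swa = swa, input_size = c(size, size, 1L), seed = seed, ...
  )
}

test_that("residual block with degenerate parameters is the identity", {
  p <- res_block_params(3L, 3L, seed = 1L)
  p$conv1$w[] <- 0
  p$conv2$w[] <- 0
  st <- res_block_state(3L)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  out <- res_block_forward(x, p, st, training = FALSE)$out
  # zero conv path + identity shortcut; BN at its (0, 1) running moments
  expect_equal(out, x, tolerance = 1e-4)
  # shape contract with a projection shortcut
  p2 <- res_block_params(8L, 16L, seed = 2L)
  x2 <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  out2 <- res_block_forward(x2, p2, res_block_state(16L), training = FALSE)$out
  expect_identical(dim(out2), c(16L, 16L, 16L, 1L))
})

test_that("residual block matches direct convolution arithmetic on a fixed case", {
  set.seed(401)
  p <- res_block_params(2L, 2L, seed = 3L)
  st <- res_block_state(2L)
  x3 <- rand_grid(4, 4, 2)
  out <- res_block_forward(array(x3, c(4, 4, 2, 1)), p, st,
    training = FALSE
  )$out
  # inference BN at (0,1) scales by 1/sqrt(1+eps); relu between stages
  sc <- 1 / sqrt(1 + 1e-5)
  h1 <- pmax(o_conv2d_same(x3, p$conv1$w, numeric(2)) * sc, 0)
  h2 <- pmax(o_conv2d_same(h1, p$conv2$w, numeric(2)) * sc, 0)
  expect_lt(rel_err(array(out, dim = c(4, 4, 2)), h2 + x3), 1e-10)
})

test_that("all five ablation variants build, forward and stay in (0, 1)", {
  variants <- list(
    list(mode = "none", swa = FALSE),
    list(mode = "pam", swa = FALSE),
    list(mode = "cbam", swa = FALSE),
    list(mode = "pcbam", swa = FALSE),
    list(mode = "pcbam", swa = TRUE)
  )
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  for (v in variants) {
    m <- build_model(toy_cfg(v$mode, v$swa))
    out <- predict(m, x)
    expect_identical(dim(out), c(32L, 32L, 1L, 1L))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("one attention block is instantiated per skip connection", {
  m <- build_model(toy_cfg("pcbam", TRUE, depth = 2L))
  expect_length(m$params$att, 2L)
  expect_named(m$params$att[[1]], c("cam", "sam", "pam"))
  m3 <- build_model(toy_cfg("cbam", FALSE, size = 32L, depth = 3L, base = 2L))
  expect_length(m3$params$att, 3L)
  expect_named(m3$params$att[[2]], c("cam", "sam"))
  m0 <- build_model(toy_cfg("none", FALSE))
  expect_length(m0$params$att, 0L)
})

test_that("builds are seed-reproducible and configs validated", {
  m1 <- build_model(toy_cfg())
  m2 <- build_model(toy_cfg())
  expect_identical(m1$params, m2$params)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(predict(m1, x), predict(m2, x))
  m3 <- build_model(toy_cfg(seed = 10L))
  expect_false(identical(m1$params, m3$params))
  expect_error(model_config(depth = 3, input_size = c(20, 20, 1)), "divisible")
  expect_error(model_config(depth = 0), "depth")
  m <- build_model(toy_cfg())
  expect_error(predict(m, array(0.1, c(16, 16, 1, 1))), "input must be")
})

test_that("parameter count is a frozen function of the configuration", {
  counts <- c(
    none = count_params(build_model(toy_cfg("none", FALSE))),
    pam = count_params(build_model(toy_cfg("pam", FALSE))),
    cbam = count_params(build_model(toy_cfg("cbam", FALSE))),
    pcbam = count_params(build_model(toy_cfg("pcbam", FALSE))),
    full = count_params(build_model(toy_cfg("pcbam", TRUE)))
  )
  expect_identical(
    counts,
    c(none = 9797L, pam = 10075L, cbam = 10041L, pcbam = 10319L, full = 11871L)
  )
})

test_that("forward_with_taps exposes the documented intermediates", {
  m <- build_model(toy_cfg("pcbam", TRUE, size = 32L, depth = 2L))
  img <- array(runif(32 * 32), c(32, 32, 1))
  r <- forward_with_taps(m, img)
  expect_identical(dim(r$prob), c(32L, 32L, 1L))
  expect_true(all(c("F_a", "F_b", "F_c", "swa", "attention1", "attention2")
  %in% names(r$taps)))
  expect_identical(dim(r$taps$F_a)[1:2], c(32L, 32L))
  expect_identical(dim(r$taps$F_c)[1:2], c(8L, 8L)) # 32 / 2^depth
  r2 <- forward_with_taps(m, img)
  expect_identical(r$taps, r2$taps) # deterministic inference
})

test_that("network gradients match central differences on scattered parameters", {
  set.seed(402)
  cfg <- toy_cfg("pcbam", TRUE, size = 16L, depth = 2L, base = 4L)
  m <- build_model(cfg)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array((runif(16 * 16 * 2) > 0.7) * 1, c(16, 16, 1, 2))
  lcfg <- loss_config()
  fw <- seg_forward(m, x, training = TRUE, cache = TRUE)
  g <- align_grads(m$params, seg_backward(
    m, fw$cache,
    batch_combined_loss_grad(y, fw$out, lcfg)
  ))
  fl <- flatten_params(m$params)
  gfl <- flatten_params(g)
  lossfn <- function(mm) {
    batch_combined_loss(y, seg_forward(mm, x, training = TRUE)$out, lcfg)
  }
  eps <- 1e-5
  for (i in sample(length(fl), 10)) {
    fp <- fl
    fp[i] <- fp[i] + eps
    fm <- fl
    fm[i] <- fm[i] - eps
    m1 <- m
    m1$params <- set_params_from(m$params, fp)
    m2 <- m
    m2$params <- set_params_from(m$params, fm)
    gn <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
    expect_lt(abs(gn - gfl[i]) / max(1e-6, abs(gn) + abs(gfl[i])), 1e-4)
  }
})

test_that("checkpoints round-trip and reject unknown versions", {
  m <- build_model(toy_cfg())
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$config), unclass(m$config))
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(predict(m2, x), predict(m, x))
  bad <- readRDS(tmp)
  bad$version <- 99L
  saveRDS(bad, tmp)
  expect_error(load_checkpoint(tmp), "version")
  expect_error(load_checkpoint(tempfile()), "not found")
})

test_that("bn re-estimation reconciles training and inference predictions", {
  set.seed(403)
  pairs <- make_pairs(6, size = 16L)
  cfg <- run_config(
    model = toy_cfg("none", FALSE, size = 16L),
    data = pairs, learning_rate = 1e-3, epochs = 8, batch_size = 6,
    seed = 7, split = c(1, 0, 0)
  )
  res <- train_model(cfg)
  m <- res$final_model
  x <- stack_images(pairs)
  pt <- seg_forward(m, x, training = TRUE)$out
  pi_raw <- seg_forward(m, x, training = FALSE)$out
  m2 <- recalibrate_bn(m, pairs, batch_size = 6)
  pi_cal <- seg_forward(m2, x, training = FALSE)$out
  expect_lt(mean(abs(pi_cal - pt)), mean(abs(pi_raw - pt)))
  expect_lt(mean(abs(pi_cal - pt)), 1e-6)
})
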