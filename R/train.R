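# Training orchestration: Adam on the combined Dice + BCE + focal loss,
# seeded end to end (initialization, shuffling), best-validation-Dice
# checkpointing and an auditable run directory (resolved config, history,
# log).

#' Run configuration
#'
#' @param model A [model_config()].
#' @param loss A [loss_config()].
#' @param data Data source: a directory path in BUSI layout, a
#'   [phantom_config()], or a list of image/mask pairs.
#' @param learning_rate Adam learning rate, default 1e-4.
#' @param epochs Training epochs, default 50.
#' @param batch_size Images per optimization step, default 8.
#' @param seed Master seed for initialization and shuffling.
#' @param split Length-3 train/val/test fractions used when `data` is not
#'   pre-split, default `c(0.70, 0.10, 0.20)`.
#' @param threshold Decision threshold for Dice tracking, default 0.5.
#' @param stop_dice Optional early-stop target: training ends once the
#'   epoch's training Dice reaches this value.
#' @param output_dir Optional run directory; when set, the checkpoint,
#'   history CSV, resolved config YAML and log are written there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = model_config(), loss = loss_config(),
                       data = phantom_config(), learning_rate = 1e-4,
                       epochs = 50L, batch_size = 8L, seed = 42L,
                       split = c(0.70, 0.10, 0.20), threshold = 0.5,
                       stop_dice = NULL, output_dir = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(
    list(
      model = model, loss = loss, data = data,
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed),
      split = split, threshold = threshold, stop_dice = stop_dice,
      output_dir = output_dir
    ),
    class = "run_config"
  )
}

resolve_data <- function(data) {
  if (inherits(data, "phantom_config")) {
    generate_phantom_dataset(data)
  } else if (is.character(data) && length(data) == 1L) {
    load_image_mask_dir(data)
  } else if (is.list(data)) {
    data
  } else {
    stop("unsupported data source", call. = FALSE)
  }
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, st$v, grads)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), st$m, st$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = st)
}

mean_batch_dice <- function(y4, p4, threshold) {
  nb <- dim(y4)[4]
  acc <- 0
  for (bi in seq_len(nb)) {
    ct <- confusion_counts(
      as.vector(y4[, , , bi]),
      as.vector(binarize(p4[, , , bi], threshold))
    )
    acc <- acc + seg_metrics(ct)$dice
  }
  acc / nb
}

dataset_dice <- function(model, pairs, threshold, batch_size = 8L) {
  evaluate_dataset(model, pairs,
    threshold = threshold,
    batch_size = batch_size
  )$summary$dice[1]
}

#' Train a segmentation model
#'
#' Minimizes the combined loss with Adam. Every stochastic step (weight
#' initialization, epoch shuffling) draws from a stream seeded by
#' `cfg$seed`, so a rerun with the same configuration reproduces the same
#' history and final parameters. The parameters achieving the best
#' validation Dice are kept as the returned model (training Dice when no
#' validation split exists).
#'
#' @param cfg A [run_config()].
#' @param pairs Optional pre-resolved list of training pairs overriding
#'   `cfg$data`; when given, no internal split is performed and validation
#'   is skipped.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `final_model` (last
#'   epoch), `history` (data.frame epoch/loss/dice columns), `best_epoch`
#'   and `train_dice` (inference-mode Dice of the best model on the
#'   training set).
#' @export
train_model <- function(cfg, pairs = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(pairs)) {
    all_pairs <- resolve_data(cfg$data)
    if (!length(all_pairs)) stop("empty dataset", call. = FALSE)
    if (length(all_pairs) >= 3L && cfg$split[1] < 1) {
      sp <- split_dataset(all_pairs, cfg$split, seed = cfg$seed)
      train_pairs <- sp$train
      val_pairs <- sp$val
    } else {
      train_pairs <- all_pairs
      val_pairs <- list()
    }
  } else {
    train_pairs <- pairs
    val_pairs <- list()
  }
  if (!length(train_pairs)) stop("empty training set", call. = FALSE)

  run_dir <- cfg$output_dir
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    if (verbose) message(line)
    log_lines <<- c(log_lines, line)
  }
  say(
    "run seed=%d | R %s | %d train / %d val images", cfg$seed,
    as.character(getRversion()), length(train_pairs), length(val_pairs)
  )

  set.seed(cfg$seed)
  model <- build_model(cfg$model)
  opt <- adam_init(model$params)
  n <- length(train_pairs)
  bs <- min(cfg$batch_size, n)
  hist <- data.frame(
    epoch = integer(), train_loss = numeric(), train_dice = numeric(),
    val_dice = numeric(), seconds = numeric()
  )
  best <- list(dice = -Inf, params = model$params, state = model$state, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- proc.time()[3]
    ord <- sample.int(n)
    ep_loss <- 0
    ep_dice <- 0
    nb <- 0L
    i0 <- 1L
    while (i0 <= n) {
      i1 <- min(n, i0 + bs - 1L)
      chunk <- train_pairs[ord[i0:i1]]
      x4 <- stack_images(chunk)
      y4 <- stack_masks(chunk)
      fw <- seg_forward(model, x4, training = TRUE, cache = TRUE)
      model$state <- fw$state
      loss <- batch_combined_loss(y4, fw$out, cfg$loss)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, "; aborting", call. = FALSE)
      }
      dprob <- batch_combined_loss_grad(y4, fw$out, cfg$loss)
      grads <- align_grads(model$params, seg_backward(model, fw$cache, dprob))
      grads <- tree_map(function(g) g / dim(x4)[4], grads)
      stp <- adam_step(model$params, grads, opt, cfg$learning_rate)
      model$params <- stp$params
      opt <- stp$state
      ep_loss <- ep_loss + loss
      ep_dice <- ep_dice + mean_batch_dice(y4, fw$out, cfg$threshold)
      nb <- nb + 1L
      i0 <- i1 + 1L
    }
    ep_loss <- ep_loss / nb
    ep_dice <- ep_dice / nb
    val_dice <- if (length(val_pairs)) {
      # score inference-mode predictions with freshly re-estimated BN
      # moments so checkpoint selection is not skewed by estimate lag
      dataset_dice(
        recalibrate_bn(model, train_pairs, bs), val_pairs,
        cfg$threshold, bs
      )
    } else {
      NA_real_
    }
    secs <- proc.time()[3] - t0
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss, train_dice = ep_dice,
      val_dice = val_dice, seconds = secs
    ))
    sel_dice <- if (is.na(val_dice)) ep_dice else val_dice
    if (sel_dice > best$dice) {
      best <- list(
        dice = sel_dice, params = model$params, state = model$state,
        epoch = ep
      )
    }
    say(
      "epoch %3d | loss %.4f | train dice %.4f | val dice %s | %.1fs",
      ep, ep_loss, ep_dice,
      if (is.na(val_dice)) "-" else sprintf("%.4f", val_dice), secs
    )
    if (!is.null(cfg$stop_dice) && ep_dice >= cfg$stop_dice) {
      say("early stop: training dice %.4f reached target %.2f", ep_dice, cfg$stop_dice)
      break
    }
  }
  best_model <- structure(
    list(config = cfg$model, params = best$params, state = best$state),
    class = "segmodel"
  )
  best_model <- recalibrate_bn(best_model, train_pairs, bs)
  train_dice <- dataset_dice(best_model, train_pairs, cfg$threshold, bs)
  say("best epoch %d | train dice (inference) %.4f", best$epoch, train_dice)
  if (!is.null(run_dir)) {
    dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(best_model, file.path(run_dir, "checkpoint.rds"))
    utils::write.csv(hist, file.path(run_dir, "history.csv"), row.names = FALSE)
    yaml::write_yaml(serialize_config(cfg), file.path(run_dir, "config.yaml"))
    writeLines(log_lines, file.path(run_dir, "log.txt"))
  }
  list(
    model = best_model, final_model = model, history = hist,
    best_epoch = best$epoch, train_dice = train_dice
  )
}

serialize_config <- function(cfg) {
  out <- unclass(cfg)
  out$model <- unclass(cfg$model)
  out$loss <- unclass(cfg$loss)
  if (inherits(cfg$data, "phantom_config")) {
    out$data <- c(list(type = "synthetic"), unclass(cfg$data))
  } else if (is.character(cfg$data)) {
    out$data <- list(type = "directory", path = cfg$data)
  } else {
    out$data <- list(type = "in-memory", n = length(cfg$data))
  }
  out
}

deserialize_config <- function(lst) {
  data <- if (identical(lst$data$type, "synthetic")) {
    do.call(phantom_config, lst$data[setdiff(names(lst$data), "type")])
  } else if (identical(lst$data$type, "directory")) {
    lst$data$path
  } else {
    stop("config data source cannot be restored from file", call. = FALSE)
  }
  run_config(
    model = do.call(model_config, lst$model),
    loss = do.call(loss_config, lst$loss),
    data = data,
    learning_rate = lst$learning_rate, epochs = lst$epochs,
    batch_size = lst$batch_size, seed = lst$seed, split = unlist(lst$split),
    threshold = lst$threshold, stop_dice = lst$stop_dice,
    output_dir = lst$output_dir
  )
}

#' Predict binary masks for images on disk or in memory
#'
#' Writes one binary mask PNG (`<id>_pred.png`, values 0/255) per input,
#' plus the probability map (`<id>_prob.png`) when requested. Re-running
#' with identical inputs produces byte-identical files.
#'
#' @param model A `segmodel` or path to a checkpoint file.
#' @param input Directory of PNGs, character vector of PNG paths, or a
#'   list of pairs with `image` elements.
#' @param out_dir Output directory.
#' @param threshold Decision threshold, default 0.5.
#' @param write_prob Also write the probability maps. Default `FALSE`.
#' @return Data frame with columns `id` and `path`, invisibly.
#' @export
predict_masks <- function(model, input, out_dir, threshold = 0.5,
                          write_prob = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  size <- model$config$input_size[1]
  items <- load_prediction_inputs(input, size)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- data.frame(id = character(), path = character())
  for (it in items) {
    prob <- seg_forward(model, it$image, training = FALSE)$out
    mk <- binarize(prob[, , 1, 1], threshold)
    path <- file.path(out_dir, paste0(it$id, "_pred.png"))
    png::writePNG(mk, path)
    if (write_prob) {
      png::writePNG(
        round(prob[, , 1, 1] * 255) / 255,
        file.path(out_dir, paste0(it$id, "_prob.png"))
      )
    }
    res <- rbind(res, data.frame(id = it$id, path = path))
  }
  invisible(res)
}

load_prediction_inputs <- function(input, size) {
  if (is.list(input) && !is.character(input)) {
    return(input)
  }
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.png$", full.names = TRUE)
  } else {
    input
  }
  files <- files[!grepl("_mask", basename(files))]
  lapply(files, function(f) {
    img <- resize_gray(to_gray(png::readPNG(f)), size)
    list(
      image = array(pmin(pmax(img, 0), 1), dim = c(size, size, 1L)),
      id = sub("\\.png$", "", basename(f))
    )
  })
}

#' Evaluate a checkpoint over a dataset
#'
#' @param model A `segmodel` or checkpoint path.
#' @param data Directory in BUSI layout, [phantom_config()] or list of
#'   pairs.
#' @param out_dir Optional directory for the metrics CSV/text report.
#' @param threshold Decision threshold, default 0.5.
#' @return The report list from [evaluate_dataset()].
#' @export
evaluate_checkpoint <- function(model, data, out_dir = NULL, threshold = 0.5) {
  if (is.character(model) && file.exists(model) && !dir.exists(model)) {
    model <- load_checkpoint(model)
  }
  pairs <- resolve_data(data)
  report <- evaluate_dataset(model, pairs, threshold = threshold)
  if (!is.null(out_dir)) write_metrics(report, out_dir)
  report
}

#' Export activation heatmaps
#'
#' Writes the channel-mean activation of each named tap, min-max
#' normalized (a constant tap maps to a flat 0.5 gray) and upsampled to
#' the input resolution, alongside the input, the predicted mask and the
#' ground-truth mask when available.
#'
#' @param model A `segmodel` or checkpoint path.
#' @param image Path to a PNG, an `H x W x 1` array, or a pair list with
#'   `image`/`mask`.
#' @param out_dir Output directory.
#' @param taps Tap names to export; default all available. Unknown names
#'   raise an error listing the available taps.
#' @param threshold Decision threshold for the predicted-mask panel.
#' @return Character vector of written files, invisibly.
#' @export
export_heatmaps <- function(model, image, out_dir, taps = NULL,
                            threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  size <- model$config$input_size[1]
  mask <- NULL
  id <- "image"
  if (is.character(image)) {
    id <- sub("\\.png$", "", basename(image))
    image <- array(
      pmin(pmax(resize_gray(to_gray(png::readPNG(image)), size), 0), 1),
      dim = c(size, size, 1L)
    )
  } else if (is.list(image) && !is.null(image$image)) {
    mask <- image$mask
    if (!is.null(image$id)) id <- image$id
    image <- image$image
  }
  r <- forward_with_taps(model, image)
  avail <- names(r$taps)
  if (is.null(taps)) taps <- avail
  unknown <- setdiff(taps, avail)
  if (length(unknown)) {
    stop(
      "unknown tap(s) ", paste(unknown, collapse = ", "),
      "; available: ", paste(avail, collapse = ", "),
      call. = FALSE
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(name, m) {
    path <- file.path(out_dir, paste0(id, "_", name, ".png"))
    png::writePNG(pmin(pmax(m, 0), 1), path)
    written <<- c(written, path)
  }
  put("input", image[, , 1])
  put("prediction", binarize(r$prob[, , 1], threshold))
  if (!is.null(mask)) put("gt", mask[, , 1])
  for (tp in taps) {
    a <- r$taps[[tp]]
    hm <- apply(array(a, dim = dim(a)[1:3]), c(1, 2), mean) # channel mean
    rng <- range(hm)
    hm <- if (rng[2] > rng[1]) (hm - rng[1]) / (rng[2] - rng[1]) else hm * 0 + 0.5
    put(paste0("tap_", tp), resize_gray(hm, size))
  }
  invisible(written)
}
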