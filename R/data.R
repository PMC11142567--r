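# Synthetic ultrasound phantoms and BUSI-layout PNG data handling.
#
# A phantom emulates the dominant appearance features of breast ultrasound:
# a smooth low-frequency echogenicity field, multiplicative unit-mean gamma
# speckle, one darker (hypoechoic) star-convex lesion, and point-spread
# blurring. The binary ground-truth mask is the exact lesion indicator
# taken before blurring, so labels are noiseless.

IMG_SIZE <- 128L

#' Phantom generator configuration
#'
#' @param n_images Number of phantoms in the dataset.
#' @param seed Base seed; each phantom is a pure function of
#'   `(seed, index)`.
#' @param lesion_area_fraction Length-2 range of the lesion area as a
#'   fraction of the image, default `c(0.02, 0.25)`.
#' @param lesion_contrast Relative mean-intensity drop inside the lesion
#'   (default 0.35; 0 disables the contrast).
#' @param speckle_strength Variance of the multiplicative unit-mean gamma
#'   speckle (default 0.15).
#' @param blur_sigma Gaussian point-spread smoothing in pixels applied to
#'   the image only (default 1.5).
#' @param shape_irregularity Amplitude of the low-order harmonic
#'   perturbation of the lesion boundary (default 0.3; 0 gives an ellipse).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_images = 100L, seed = 1L,
                           lesion_area_fraction = c(0.02, 0.25),
                           lesion_contrast = 0.35,
                           speckle_strength = 0.15,
                           blur_sigma = 1.5,
                           shape_irregularity = 0.3) {
  if (n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  if (length(lesion_area_fraction) != 2L ||
    any(lesion_area_fraction <= 0) || any(lesion_area_fraction >= 1) ||
    diff(lesion_area_fraction) < 0) {
    stop("lesion_area_fraction must be an increasing range inside (0, 1)",
      call. = FALSE
    )
  }
  if (lesion_area_fraction[2] > 0.4) {
    stop("lesion_area_fraction above 0.4 cannot be placed inside the frame",
      call. = FALSE
    )
  }
  stopifnot(
    lesion_contrast >= 0, lesion_contrast < 1,
    speckle_strength > 0, blur_sigma >= 0, shape_irregularity >= 0
  )
  structure(
    list(
      n_images = as.integer(n_images), seed = as.integer(seed),
      lesion_area_fraction = as.numeric(lesion_area_fraction),
      lesion_contrast = lesion_contrast,
      speckle_strength = speckle_strength,
      blur_sigma = blur_sigma,
      shape_irregularity = shape_irregularity
    ),
    class = "phantom_config"
  )
}

#' Generate one synthetic ultrasound phantom
#'
#' Deterministic in `(cfg$seed, index)`. The image is quantized to 8-bit
#' levels so that a PNG round trip through [make_synthetic()] and
#' [load_image_mask_dir()] is lossless.
#'
#' @param cfg A [phantom_config()].
#' @param index Phantom index (1-based).
#' @return List with `image` (128 x 128 x 1, values in \[0, 1\]), `mask`
#'   (128 x 128 x 1, strictly 0/1), `id` and `class_label = "synthetic"`.
#' @export
generate_phantom <- function(cfg, index) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- IMG_SIZE
  with_seed(derive_seed(cfg$seed, index), {
    gx <- matrix(rep(seq_len(n), n), n, n) / n
    gy <- matrix(rep(seq_len(n), each = n), n, n) / n
    # smooth echogenicity field: a few random low-frequency cosines
    bg <- matrix(0.55, n, n)
    for (k in 1:4) {
      fx <- stats::runif(1, 0.5, 2.5)
      fy <- stats::runif(1, 0.5, 2.5)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.02, 0.06)
      bg <- bg + amp * cos(2 * pi * (fx * gx + fy * gy) + ph)
    }
    # star-convex lesion: perturbed rotated ellipse
    frac <- stats::runif(1, cfg$lesion_area_fraction[1], cfg$lesion_area_fraction[2])
    r0 <- sqrt(frac * n * n / pi)
    rho <- stats::runif(1, 0.7, 1.4)
    ra <- r0 * sqrt(rho)
    rb <- r0 / sqrt(rho)
    rmax <- max(ra, rb) * (1 + cfg$shape_irregularity)
    cx <- stats::runif(1, rmax + 2, n - rmax - 2)
    cy <- stats::runif(1, rmax + 2, n - rmax - 2)
    th0 <- stats::runif(1, 0, pi)
    aj <- stats::rnorm(4, 0, 0.5 / (2:5))
    bj <- stats::rnorm(4, 0, 0.5 / (2:5))
    dx <- (gx * n - cx)
    dy <- (gy * n - cy)
    xr <- cos(th0) * dx + sin(th0) * dy
    yr <- -sin(th0) * dx + cos(th0) * dy
    re <- sqrt((xr / ra)^2 + (yr / rb)^2) # elliptical radius, 1 at boundary
    ang <- atan2(yr, xr)
    pert <- 0
    for (j in 2:5) {
      pert <- pert + aj[j - 1] * cos(j * ang) + bj[j - 1] * sin(j * ang)
    }
    boundary <- pmax(0.2, 1 + cfg$shape_irregularity * pert)
    mask <- (re <= boundary) * 1
    img <- bg * (1 - cfg$lesion_contrast * mask)
    # unit-mean gamma speckle with variance = speckle_strength
    shape <- 1 / cfg$speckle_strength
    img <- img * matrix(stats::rgamma(n * n, shape = shape, rate = shape), n, n)
    if (cfg$blur_sigma > 0) {
      img <- gaussian_blur(img, cfg$blur_sigma)
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255 # 8-bit levels: PNG round trip is exact
    list(
      image = array(img, dim = c(n, n, 1L)),
      mask = array(mask, dim = c(n, n, 1L)),
      id = sprintf("synthetic_%04d", as.integer(index)),
      class_label = "synthetic"
    )
  })
}

gaussian_blur <- function(m, sigma) {
  im <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  matrix(EBImage::imageData(im), nrow(m), ncol(m))
}

#' Generate a phantom dataset
#'
#' @param cfg A [phantom_config()].
#' @return List of `cfg$n_images` image/mask pairs.
#' @export
generate_phantom_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_images), function(i) generate_phantom(cfg, i))
}

#' Write a synthetic dataset in BUSI layout
#'
#' Creates `<dir>/synthetic/<id>.png` plus `<id>_mask.png` for every
#' phantom, so the dataset round-trips through [load_image_mask_dir()].
#'
#' @param cfg A [phantom_config()].
#' @param dir Output root directory.
#' @return The class directory path, invisibly.
#' @export
make_synthetic <- function(cfg, dir) {
  cls <- file.path(dir, "synthetic")
  dir.create(cls, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(cfg$n_images)) {
    pr <- generate_phantom(cfg, i)
    png::writePNG(pr$image[, , 1], file.path(cls, paste0(pr$id, ".png")))
    png::writePNG(pr$mask[, , 1], file.path(cls, paste0(pr$id, "_mask.png")))
  }
  invisible(cls)
}

to_gray <- function(a) {
  if (length(dim(a)) == 2L) {
    return(a)
  }
  if (dim(a)[3] >= 3L) {
    0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  } else {
    a[, , 1]
  }
}

resize_gray <- function(m, size, nearest = FALSE) {
  if (all(dim(m) == size)) {
    return(m)
  }
  im <- EBImage::Image(m)
  out <- if (nearest) {
    EBImage::resize(im, w = size, h = size, filter = "none")
  } else {
    EBImage::resize(im, w = size, h = size)
  }
  matrix(EBImage::imageData(out), size, size)
}

#' Load an image/mask directory in BUSI layout
#'
#' Expects `<root>/<class>/<name>.png` with sibling `<name>_mask*.png`
#' files; multiple mask files per image are combined with a pixel-wise OR.
#' Images are converted to grayscale (luminance), resized to 128 x 128
#' (bilinear), and masks resized with nearest neighbor then re-binarized
#' at 0.5. Images without any mask are skipped and reported in the
#' `"skipped"` attribute of the result.
#'
#' @param root Dataset root directory.
#' @param include_normal Include a `normal` class directory (tumor-free
#'   images) if present; default `FALSE`.
#' @param size Output side length in pixels, default 128.
#' @return List of pairs (`image`, `mask`, `id`, `class_label`), with
#'   attribute `skipped` listing mask-less image paths.
#' @export
load_image_mask_dir <- function(root, include_normal = FALSE, size = IMG_SIZE) {
  if (!dir.exists(root)) stop("directory not found: ", root, call. = FALSE)
  classes <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (!length(classes)) {
    stop("no class subdirectories under ", root, call. = FALSE)
  }
  if (!include_normal) classes <- setdiff(classes, "normal")
  pairs <- list()
  skipped <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.png$"))
    imgs <- files[!grepl("_mask", files)]
    for (f in imgs) {
      base <- sub("\\.png$", "", f)
      maskf <- files[grepl(
        paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", base), "_mask"),
        files
      )]
      ipath <- file.path(root, cl, f)
      if (!length(maskf)) {
        skipped <- c(skipped, ipath)
        next
      }
      img <- tryCatch(png::readPNG(ipath), error = function(e) {
        stop("unreadable PNG: ", ipath, " (", conditionMessage(e), ")",
          call. = FALSE
        )
      })
      img <- resize_gray(to_gray(img), size)
      img <- pmin(pmax(img, 0), 1)
      mk <- NULL
      for (mf in maskf) {
        m1 <- to_gray(png::readPNG(file.path(root, cl, mf)))
        mk <- if (is.null(mk)) m1 else pmax(mk, m1) # union of mask files
      }
      mk <- (resize_gray((mk >= 0.5) * 1, size, nearest = TRUE) >= 0.5) * 1
      pairs[[length(pairs) + 1L]] <- list(
        image = array(img, dim = c(size, size, 1L)),
        mask = array(mk, dim = c(size, size, 1L)),
        id = base, class_label = cl
      )
    }
  }
  attr(pairs, "skipped") <- skipped
  pairs
}

#' Shuffled train/validation/test split
#'
#' Sizes are `floor(f * n)` per fraction with the remainder assigned to
#' the training set; membership is an exclusive, exhaustive, seeded
#' shuffle.
#'
#' @param pairs List of items to split.
#' @param fractions Length-3 fractions `(train, val, test)` summing to 1;
#'   default `c(0.70, 0.10, 0.20)`.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(pairs, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  n <- length(pairs)
  if (n < 3L) stop("need at least 3 items to split", call. = FALSE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be length 3 and sum to 1", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n))
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  n_te <- floor(fractions[3] * n)
  n_tr <- n_tr + (n - n_tr - n_va - n_te) # remainder to train
  list(
    train = pairs[idx[seq_len(n_tr)]],
    val = pairs[idx[n_tr + seq_len(n_va)]],
    test = pairs[idx[n_tr + n_va + seq_len(n_te)]]
  )
}

#' Seeded k-fold partition
#'
#' @param pairs List of items.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train = ..., test = ...)`;
#'   test folds are disjoint, exhaustive and differ in size by at most 1.
#' @export
kfold_split <- function(pairs, k = 5L, seed = 1L) {
  n <- length(pairs)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k items", call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(f) {
    test_idx <- idx[starts[f]:ends[f]]
    list(train = pairs[setdiff(idx, test_idx)], test = pairs[test_idx])
  })
}
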