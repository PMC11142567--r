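# Phantom generator, BUSI-layout I/O and dataset splitting.

test_that("phantom generation is a pure function of (seed, index)", {
  cfg <- phantom_config(n_images = 2, seed = 11)
  a <- generate_phantom(cfg, 1)
  b <- generate_phantom(cfg, 1)
  expect_identical(a, b)
  c2 <- generate_phantom(cfg, 2)
  expect_false(identical(a$image, c2$image))
  other <- generate_phantom(phantom_config(n_images = 2, seed = 12), 1)
  expect_false(identical(a$image, other$image))
  # generating phantom 1 must not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_phantom(cfg, 1))
  expect_identical(runif(1), before)
})

test_that("phantoms have binary masks, bounded images and a hypoechoic lesion", {
  cfg <- phantom_config(n_images = 30, seed = 21)
  darker <- 0
  for (i in 1:30) {
    pr <- generate_phantom(cfg, i)
    expect_identical(dim(pr$image), c(128L, 128L, 1L))
    expect_identical(dim(pr$mask), c(128L, 128L, 1L))
    expect_true(all(pr$mask %in% c(0, 1)))
    expect_true(all(pr$image >= 0 & pr$image <= 1))
    frac <- mean(pr$mask)
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.30)
    if (mean(pr$image[pr$mask == 1]) < mean(pr$image[pr$mask == 0])) {
      darker <- darker + 1
    }
  }
  expect_gte(darker / 30, 0.95)
})

test_that("zero lesion contrast removes the intensity gap", {
  cfg <- phantom_config(n_images = 10, seed = 31, lesion_contrast = 0)
  gaps <- vapply(1:10, function(i) {
    pr <- generate_phantom(cfg, i)
    mean(pr$image[pr$mask == 1]) - mean(pr$image[pr$mask == 0])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.02)
})

test_that("phantom config rejects infeasible settings", {
  expect_error(phantom_config(n_images = 0), "n_images")
  expect_error(phantom_config(lesion_area_fraction = c(0.3, 0.2)), "range")
  expect_error(phantom_config(lesion_area_fraction = c(0.2, 0.8)), "frame")
})

test_that("synthetic datasets round-trip through the BUSI-layout loader", {
  cfg <- phantom_config(n_images = 5, seed = 41)
  root <- tempfile()
  make_synthetic(cfg, root)
  expect_length(list.files(file.path(root, "synthetic"), pattern = "png$"), 10L)
  pairs <- load_image_mask_dir(root)
  expect_length(pairs, 5L)
  ref <- generate_phantom_dataset(cfg)
  ord <- match(vapply(ref, `[[`, "", "id"), vapply(pairs, `[[`, "", "id"))
  for (i in seq_along(ref)) {
    expect_equal(pairs[[ord[i]]]$image, ref[[i]]$image, tolerance = 1e-12)
    expect_identical(pairs[[ord[i]]]$mask == 1, ref[[i]]$mask == 1)
  }
  # regeneration writes byte-identical files
  root2 <- tempfile()
  make_synthetic(cfg, root2)
  f1 <- list.files(file.path(root, "synthetic"), full.names = TRUE)
  f2 <- list.files(file.path(root2, "synthetic"), full.names = TRUE)
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", 1e6), readBin(f2[k], "raw", 1e6))
  }
  # loading twice is idempotent
  expect_identical(load_image_mask_dir(root), pairs)
})

test_that("loader unions multiple masks, skips maskless images, excludes normals", {
  root <- tempfile()
  dir.create(file.path(root, "benign"), recursive = TRUE)
  dir.create(file.path(root, "normal"), recursive = TRUE)
  img <- matrix(runif(128 * 128), 128, 128)
  m1 <- matrix(0, 128, 128)
  m1[10:40, 10:40] <- 1
  m2 <- matrix(0, 128, 128)
  m2[30:60, 50:90] <- 1
  png::writePNG(img, file.path(root, "benign", "case1.png"))
  png::writePNG(m1, file.path(root, "benign", "case1_mask.png"))
  png::writePNG(m2, file.path(root, "benign", "case1_mask_1.png"))
  png::writePNG(img, file.path(root, "benign", "case2.png")) # no mask
  png::writePNG(img, file.path(root, "normal", "case3.png"))
  png::writePNG(m1 * 0, file.path(root, "normal", "case3_mask.png"))
  pairs <- load_image_mask_dir(root)
  expect_length(pairs, 1L)
  expect_identical(pairs[[1]]$id, "case1")
  expect_identical(pairs[[1]]$mask[, , 1], pmax(m1, m2)) # pixelwise OR
  expect_match(attr(pairs, "skipped"), "case2")
  with_norm <- load_image_mask_dir(root, include_normal = TRUE)
  expect_length(with_norm, 2L)
})

test_that("loader converts color and rescales sizes deterministically", {
  root <- tempfile()
  dir.create(file.path(root, "malignant"), recursive = TRUE)
  rgb <- array(runif(64 * 80 * 3), c(64, 80, 3))
  mk <- matrix(0, 64, 80)
  mk[20:40, 30:60] <- 1
  png::writePNG(rgb, file.path(root, "malignant", "c.png"))
  png::writePNG(mk, file.path(root, "malignant", "c_mask.png"))
  pairs <- load_image_mask_dir(root)
  expect_identical(dim(pairs[[1]]$image), c(128L, 128L, 1L))
  expect_true(all(pairs[[1]]$mask %in% c(0, 1)))
  expect_gt(mean(pairs[[1]]$mask), 0.05) # lesion survives resizing
  expect_identical(pairs[[1]]$class_label, "malignant")
})

test_that("split_dataset produces exhaustive disjoint seeded splits", {
  pairs <- as.list(letters[1:10])
  sp <- split_dataset(pairs, seed = 5)
  expect_identical(lengths(sp), c(train = 7L, val = 1L, test = 2L))
  expect_identical(split_dataset(pairs, seed = 5), sp)
  expect_false(identical(split_dataset(pairs, seed = 6), sp))
  set.seed(701)
  for (i in 1:10) {
    n <- sample(3:60, 1)
    items <- as.list(seq_len(n))
    spi <- split_dataset(items, seed = i)
    all_items <- c(spi$train, spi$val, spi$test)
    expect_identical(sort(unlist(all_items)), seq_len(n))
    expect_identical(length(all_items), n)
  }
  expect_error(split_dataset(as.list(1:2)), "at least 3")
  expect_error(split_dataset(pairs, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("kfold_split partitions exactly with near-equal folds", {
  pairs <- as.list(1:10)
  folds <- kfold_split(pairs, k = 5, seed = 3)
  expect_length(folds, 5L)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 2L))
  expect_identical(sort(unlist(lapply(folds, function(f) unlist(f$test)))), 1:10)
  for (f in folds) {
    expect_length(intersect(unlist(f$train), unlist(f$test)), 0L)
    expect_identical(sort(unlist(c(f$train, f$test))), 1:10)
  }
  expect_identical(kfold_split(pairs, k = 5, seed = 3), folds)
  set.seed(702)
  for (i in 1:8) {
    n <- sample(5:40, 1)
    k <- sample(2:5, 1)
    if (n < k) next
    fl <- kfold_split(as.list(seq_len(n)), k = k, seed = i)
    sizes <- vapply(fl, function(f) length(f$test), 0L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(sort(unlist(lapply(fl, function(f) unlist(f$test)))), seq_len(n))
  }
  expect_error(kfold_split(as.list(1:3), k = 5), "at least k")
  expect_error(kfold_split(as.list(1:10), k = 1), "k must be")
})
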