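# Windowing, resizing, patient splits, and the NIfTI/PNG/DICOM round trips.

test_that("apply_window is the documented linear ramp with clipping", {
  w <- window_spec(width = 1500, center = 600)
  # midpoint of the ramp
  expect_equal(apply_window(matrix(600, 8, 8), w), matrix(0.5, 8, 8))
  # clipping limits
  expect_equal(apply_window(matrix(600 - 750, 8, 8), w), matrix(0, 8, 8))
  expect_equal(apply_window(matrix(600 + 750, 8, 8), w), matrix(1, 8, 8))
  expect_equal(apply_window(matrix(-5000, 8, 8), w), matrix(0, 8, 8))
  # random HU array against independent elementwise evaluation
  set.seed(3)
  hu <- matrix(runif(400, -1200, 1500), 20, 20)
  got <- apply_window(hu, w)
  expected <- matrix(vapply(as.vector(hu), function(v) {
    min(max((v - (600 - 1500 / 2)) / 1500, 0), 1)
  }, numeric(1)), 20, 20)
  expect_equal(got, expected)
})

test_that("windowing is monotone and acts as identity on an identity window", {
  set.seed(4)
  hu <- sort(runif(100, -1100, 1600))
  w <- window_spec(1500, 600)
  out <- apply_window(matrix(hu, 10, 10), w)
  expect_true(all(diff(as.vector(out)[order(hu)]) >= 0))
  # identity window over [0,1]: width 1, center 0.5 maps x -> x
  idw <- window_spec(width = 1, center = 0.5)
  x <- matrix(runif(64), 8, 8)
  expect_equal(apply_window(x, idw), x, tolerance = 1e-12)
  expect_error(window_spec(width = -1), "width")
})

test_that("bilinear resize preserves constants, hits the protocol shapes, and matches a loop oracle", {
  expect_equal(resize_to_model(matrix(0.37, 32, 32), 16), matrix(0.37, 16, 16))
  big <- matrix(runif(512 * 512), 512, 512)
  expect_equal(dim(resize_to_model(big, 256)), c(256L, 256L))
  expect_error(resize_to_model(big, 4), ">= 8")

  # independent double-loop bilinear oracle, pixel-center aligned
  set.seed(5)
  img <- matrix(runif(16 * 16), 16, 16)
  got <- resize_to_model(img, 8)
  oracle <- matrix(0, 8, 8)
  interp1 <- function(vec, p) {
    j0 <- floor(p); w <- p - j0
    j0c <- min(max(j0, 1), length(vec)); j1c <- min(max(j0 + 1, 1), length(vec))
    (1 - w) * vec[j0c] + w * vec[j1c]
  }
  for (i in 1:8) for (j in 1:8) {
    pr <- (i - 0.5) * 16 / 8 + 0.5
    pc <- (j - 0.5) * 16 / 8 + 0.5
    rows <- vapply(1:16, function(r) interp1(img[r, ], pc), numeric(1))
    oracle[i, j] <- interp1(rows, pr)
  }
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("mask resize keeps values binary", {
  expect_equal(resize_mask(matrix(1, 32, 32), 16), matrix(1, 16, 16))
  expect_equal(resize_mask(matrix(0, 32, 32), 16), matrix(0, 16, 16))
  set.seed(6)
  m <- matrix(rbinom(24 * 24, 1, 0.3), 24, 24)
  for (side in c(8, 16, 48)) {
    out <- resize_mask(m, side)
    expect_true(all(out %in% c(0, 1)))
    expect_equal(dim(out), c(side, side))
  }
})

test_that("patient splits are deterministic, disjoint, and a partition", {
  ids <- sprintf("P%03d", 1:60)
  sp <- split_by_patient(ids, counts = c(50, 4, 6), seed = 11)
  expect_length(sp$train_ids, 50)
  expect_length(sp$val_ids, 4)
  expect_length(sp$test_ids, 6)
  all_back <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_back, ids)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(intersect(sp$val_ids, sp$test_ids), 0)
  sp2 <- split_by_patient(ids, counts = c(50, 4, 6), seed = 11)
  expect_identical(sp, sp2)
  sp3 <- split_by_patient(ids, counts = c(50, 4, 6), seed = 12)
  expect_false(identical(sp$train_ids, sp3$train_ids))
  expect_error(split_by_patient(ids, counts = c(50, 4, 5)), "sum")
})

test_that("slices of one patient never cross split boundaries", {
  spec <- phantom_spec(n_samples = 12, side = 32, slices_per_patient = 3, seed = 2)
  pats <- vapply(1:12, function(i) generate_sample(spec, i)$patient_id, character(1))
  sp <- split_by_patient(unique(pats), counts = c(2, 1, 1), seed = 5)
  assign_of <- function(p) {
    c("train", "val", "test")[c(p %in% sp$train_ids, p %in% sp$val_ids, p %in% sp$test_ids)]
  }
  by_slice <- vapply(pats, assign_of, character(1))
  for (p in unique(pats)) {
    expect_length(unique(by_slice[pats == p]), 1)
  }
})

test_that("NIfTI volumes round-trip and split into slices", {
  vol <- array(round(runif(16 * 16 * 4, -1000, 400)), c(16, 16, 4))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, path)
  slices <- read_nifti_volume(path)
  expect_length(slices, 4)
  for (k in 1:4) {
    expect_s3_class(slices[[k]], "ct_image")
    expect_equal(slices[[k]]$pixels, vol[, , k])
    expect_equal(slices[[k]]$slice_index, k)
  }
  # non-3-D input refuses
  path2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 2, 2))), path2)
  expect_error(read_nifti_volume(path2), "3-D")
})

test_that("PNG masks round-trip as binary", {
  set.seed(8)
  m <- matrix(rbinom(64 * 64, 1, 0.2), 64, 64)
  path <- tempfile(fileext = ".png")
  write_mask_png(m, path)
  back <- read_mask_png(path)
  expect_equal(back, m, ignore_attr = TRUE)
  expect_true(all(back %in% c(0, 1)))
  expect_error(write_mask_png(matrix(0.5, 4, 4), tempfile(fileext = ".png")), "binary")
})

test_that("ct_image enforces its invariants", {
  expect_error(ct_image(matrix(0, 4, 4)), ">= 8")
  expect_error(ct_image(matrix(c(NA, rep(0, 63)), 8, 8)), "finite")
  img <- ct_image(matrix(0, 8, 8), patient_id = "P1", slice_index = 3)
  expect_equal(img$slice_index, 3L)
})
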