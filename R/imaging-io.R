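# CT input-output and preprocessing: Hounsfield windowing, model resizing,
# NIfTI/PNG readers and writers, patient-level splits.
#
# Row/column convention, fixed package-wide: rows index the image top to
# bottom, columns left to right; R matrices are indexed [row, column].

#' CT image container
#'
#' A single axial slice of HU (Hounsfield unit) values with acquisition
#' metadata.
#'
#' @param pixels Numeric matrix of HU values, both sides >= 8, all finite.
#' @param patient_id Opaque patient identifier string.
#' @param slice_index Integer >= 0, position along the acquisition axis.
#' @param pixel_spacing Optional numeric length-2 (row mm, column mm).
#' @return Object of class `ct_image`.
#' @export
ct_image <- function(pixels, patient_id = "unknown", slice_index = 0L,
                     pixel_spacing = NULL) {
  if (!is.matrix(pixels) || any(dim(pixels) < 8L)) {
    stop("pixels must be a matrix with both sides >= 8", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("HU values must be finite", call. = FALSE)
  if (slice_index < 0L) stop("slice_index must be >= 0", call. = FALSE)
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index),
                 pixel_spacing = pixel_spacing),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %dx%d HU [%g, %g], patient %s, slice %d\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              x$patient_id, x$slice_index))
  invisible(x)
}

#' Hounsfield display window
#'
#' Defaults follow the study protocol's printed pair (width 1500, center
#' 600). Note that the conventional lung window places the center at -600 HU;
#' [lung_window()] returns that choice, which the phantom training pipeline
#' uses so that lung tissue stays inside the mapped range.
#'
#' @param width Window width in HU (> 0).
#' @param center Window center in HU.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(width = 1500, center = 600) {
  if (width <= 0) stop("window width must be > 0", call. = FALSE)
  structure(list(width = width, center = center), class = "window_spec")
}

#' @rdname window_spec
#' @export
lung_window <- function() window_spec(width = 1500, center = -600)

#' Apply an HU window
#'
#' Linear ramp with clipping:
#' `value = clip((HU - (center - width/2)) / width, 0, 1)`. Monotone
#' non-decreasing in HU.
#'
#' @param img A [ct_image()] or an HU matrix.
#' @param w A [window_spec()].
#' @return Numeric matrix in `[0, 1]`, same shape as the input.
#' @export
apply_window <- function(img, w = window_spec()) {
  if (inherits(img, "ct_image")) img <- img$pixels
  if (!inherits(w, "window_spec")) stop("w must be a window_spec", call. = FALSE)
  pmin(pmax((img - (w$center - w$width / 2)) / w$width, 0), 1)
}

# separable bilinear weights mapping n_in samples to n_out, pixel-center
# aligned; rows sum to 1
.bilinear_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5   # continuous 1-based index
  j0 <- floor(p)
  w1 <- p - j0
  j0c <- pmin(pmax(j0, 1L), n_in)
  j1c <- pmin(pmax(j0 + 1L, 1L), n_in)
  for (i in seq_len(n_out)) {
    W[i, j0c[i]] <- W[i, j0c[i]] + (1 - w1[i])
    W[i, j1c[i]] <- W[i, j1c[i]] + w1[i]
  }
  W
}

#' Resize a normalized image to the model grid
#'
#' Separable bilinear interpolation with pixel-center alignment (the same
#' coordinate frame the decoder uses). The study protocol resizes 512x512
#' acquisitions to 256x256.
#'
#' @param img Numeric matrix (normalized image).
#' @param side Output side length (>= 8).
#' @return `side x side` numeric matrix.
#' @export
resize_to_model <- function(img, side = 256L) {
  side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8", call. = FALSE)
  if (!is.matrix(img)) stop("img must be a matrix", call. = FALSE)
  Wr <- .bilinear_weights(side, nrow(img))
  Wc <- .bilinear_weights(side, ncol(img))
  Wr %*% img %*% t(Wc)
}

#' Resize a binary mask
#'
#' Nearest-neighbor interpolation (pixel-center aligned), so values stay in
#' \{0, 1\}.
#'
#' @param mask 0/1 matrix.
#' @param side Output side length (>= 8).
#' @return `side x side` 0/1 matrix.
#' @export
resize_mask <- function(mask, side = 256L) {
  side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8", call. = FALSE)
  ri <- .nearest_axis(pixel_centers(side), nrow(mask))
  ci <- .nearest_axis(pixel_centers(side), ncol(mask))
  mask[ri, ci, drop = FALSE]
}

#' Patient-level dataset split
#'
#' Randomly partitions patient identifiers into train/validation/test sets of
#' the requested sizes (the study uses 50/4/6 of its 60 patients).
#' Deterministic for a given seed; because the split is over patients, no two
#' slices of one patient can land in different sets.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param counts Integer length-3 `(train, val, test)`, summing to
#'   `length(patient_ids)`.
#' @param seed Integer seed.
#' @return Object of class `dataset_split`: list with `train_ids`, `val_ids`,
#'   `test_ids`.
#' @export
split_by_patient <- function(patient_ids, counts = c(50L, 4L, 6L), seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  if (sum(counts) != length(patient_ids)) {
    stop("counts sum to ", sum(counts), " but there are ", length(patient_ids),
         " patients", call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample(patient_ids)
  structure(list(train_ids = sort(perm[seq_len(counts[1])]),
                 val_ids = sort(perm[counts[1] + seq_len(counts[2])]),
                 test_ids = sort(perm[counts[1] + counts[2] + seq_len(counts[3])])),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d patients\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

## ---- NIfTI ----

#' Read a NIfTI volume as axial CT slices
#'
#' HU scaling (scl slope/intercept) is applied per the header. Slices are
#' taken along the third axis with increasing `slice_index`.
#'
#' @param path Path to a 3-D `.nii` / `.nii.gz` file.
#' @param patient_id Identifier attached to every slice (defaults to the
#'   file name).
#' @return List of [ct_image()] objects, one per slice.
#' @export
read_nifti_volume <- function(path, patient_id = NULL) {
  v <- RNifti::readNifti(path)
  a <- as.array(v)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)   # single-slice volume
  if (length(dim(a)) != 3L) {
    stop("expected a 3-D volume, got ", length(dim(a)), " dimensions", call. = FALSE)
  }
  if (is.null(patient_id)) patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  pixdim <- tryCatch(RNifti::pixdim(v)[1:2], error = function(e) NULL)
  lapply(seq_len(dim(a)[3]), function(k) {
    ct_image(a[, , k], patient_id = patient_id, slice_index = k,
             pixel_spacing = pixdim)
  })
}

#' Write an HU volume (or label volume) as NIfTI
#'
#' @param vol 3-D numeric array, or a matrix (written as a single-slice
#'   volume).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Storage type; the default `"double"` round-trips HU values
#'   bit-exactly, `"uint8"` suits label volumes.
#' @export
write_nifti_volume <- function(vol, path, datatype = "double") {
  if (is.matrix(vol)) dim(vol) <- c(dim(vol), 1L)
  RNifti::writeNifti(RNifti::asNifti(vol), path, datatype = datatype)
  invisible(path)
}

## ---- PNG masks ----

#' Read a binary mask from PNG
#'
#' Any nonzero pixel (first channel for color PNGs) is lesion.
#'
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (a > 0) * 1L
}

#' Write a binary mask as 8-bit PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)", call. = FALSE)
  png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
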