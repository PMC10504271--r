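# Synthetic chest-CT phantoms: a soft-tissue body ellipse on an air
# background, two low-attenuation lung fields, and (with configurable
# probability) a crescent-shaped pneumothorax along one lung's rim at even
# lower attenuation, plus the paired binary lesion mask. The phantoms stand
# in for clinical data so the whole pipeline is exercisable offline.

#' Phantom generator specification
#'
#' HU anchors are realistic CT values: air -1000, collapsed-lung parenchyma
#' around -800, pleural air (pneumothorax) around -950, soft tissue +40.
#' `lesion_probability` defaults to 0.72, matching a clinical slice mix in
#' which roughly 12.5k of 17.3k axial slices carry a lesion.
#'
#' @param n_samples Number of image/mask pairs the spec describes.
#' @param side Raw image side in pixels (clinical acquisitions are 512).
#' @param lesion_probability Probability a sample carries a pneumothorax.
#' @param lesion_area_range Crescent area as a fraction of the affected lung
#'   ellipse, `(min, max)`.
#' @param hu_body,hu_lung,hu_pneumo HU anchors; must satisfy
#'   `hu_pneumo < hu_lung < hu_body`.
#' @param noise_sd Additive Gaussian noise, HU.
#' @param slices_per_patient Consecutive samples sharing one patient-style id
#'   (for patient-level split tests).
#' @param seed Master seed; each sample is derived from `(seed, index)` so
#'   generation order does not matter.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_samples = 64L, side = 512L, lesion_probability = 0.72,
                         lesion_area_range = c(0.08, 0.35),
                         hu_body = 40, hu_lung = -800, hu_pneumo = -950,
                         noise_sd = 20, slices_per_patient = 1L, seed = 1L) {
  if (!(hu_pneumo < hu_lung && hu_lung < hu_body)) {
    stop("HU anchors must satisfy hu_pneumo < hu_lung < hu_body", call. = FALSE)
  }
  if (lesion_probability < 0 || lesion_probability > 1) {
    stop("lesion_probability must be in [0, 1]", call. = FALSE)
  }
  if (length(lesion_area_range) != 2L || lesion_area_range[1] <= 0 ||
      lesion_area_range[2] >= 0.9 || diff(lesion_area_range) < 0) {
    stop("lesion_area_range must be increasing and inside (0, 0.9)", call. = FALSE)
  }
  if (side < 16L) stop("side must be >= 16", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), side = as.integer(side),
                 lesion_probability = lesion_probability,
                 lesion_area_range = lesion_area_range,
                 hu_body = hu_body, hu_lung = hu_lung, hu_pneumo = hu_pneumo,
                 noise_sd = noise_sd,
                 slices_per_patient = as.integer(slices_per_patient),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# inside-ellipse indicator over the pixel grid; center/axes in [0,1] units
.ellipse_mask <- function(side, center, axes, coords) {
  ((coords$r - center[1]) / axes[1])^2 + ((coords$c - center[2]) / axes[2])^2 <= 1
}

.phantom_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

#' Generate one phantom sample
#'
#' Deterministic given `(spec$seed, index)`. The pneumothorax, when present,
#' is the set difference of a lung ellipse and a shrunken, rim-shifted inner
#' ellipse: a crescent of pleural air hugging the lung boundary, which is the
#' typical CT appearance of the condition.
#'
#' @param spec A [phantom_spec()].
#' @param index Sample index (1-based).
#' @return List with `image` (a [ct_image()]), `mask` (0/1 matrix),
#'   `has_lesion`, `patient_id`, `lesion_area` (pixels).
#' @export
generate_sample <- function(spec, index = 1L) {
  set.seed(.phantom_seed(spec$seed, index))
  side <- spec$side
  cen <- pixel_centers(side)
  coords <- list(r = matrix(cen, side, side), c = matrix(cen, side, side, byrow = TRUE))

  hu <- matrix(-1000, side, side)              # air background
  body_c <- c(0.52 + stats::runif(1, -0.02, 0.02), 0.5 + stats::runif(1, -0.02, 0.02))
  body_ax <- c(0.34 + stats::runif(1, -0.03, 0.03), 0.42 + stats::runif(1, -0.03, 0.03))
  body <- .ellipse_mask(side, body_c, body_ax, coords)
  hu[body] <- spec$hu_body

  lungs <- vector("list", 2L)
  for (k in 1:2) {
    lc <- c(body_c[1] + stats::runif(1, -0.02, 0.02),
            body_c[2] + (if (k == 1) -1 else 1) * (0.19 + stats::runif(1, -0.02, 0.02)))
    la <- c(0.21 + stats::runif(1, -0.02, 0.02), 0.13 + stats::runif(1, -0.015, 0.015))
    lungs[[k]] <- list(center = lc, axes = la,
                       mask = .ellipse_mask(side, lc, la, coords) & body)
    hu[lungs[[k]]$mask] <- spec$hu_lung
  }

  mask <- matrix(0L, side, side)
  has_lesion <- stats::runif(1) < spec$lesion_probability
  if (has_lesion) {
    # rasterization at coarse grids can void a thin crescent; redraw the
    # geometry (deterministically, same RNG stream) a bounded number of times
    crescent <- NULL
    for (attempt in 1:20) {
      k <- sample(1:2, 1L)
      lung <- lungs[[k]]
      a <- stats::runif(1, spec$lesion_area_range[1], spec$lesion_area_range[2])
      f <- sqrt(1 - a)                         # inner ellipse scale
      theta <- stats::runif(1, 0, 2 * pi)
      shift <- (1 - f) * lung$axes * c(cos(theta), sin(theta))
      inner <- .ellipse_mask(side, lung$center + shift, f * lung$axes, coords)
      cand <- lung$mask & !inner
      if (any(cand)) {
        crescent <- cand
        break
      }
    }
    if (is.null(crescent)) stop("degenerate lesion geometry: empty crescent", call. = FALSE)
    hu[crescent] <- spec$hu_pneumo
    mask[crescent] <- 1L
  }

  if (spec$noise_sd > 0) {
    hu <- hu + matrix(stats::rnorm(side * side, sd = spec$noise_sd), side, side)
  }
  patient <- sprintf("P%04d", (as.integer(index) - 1L) %/% spec$slices_per_patient + 1L)
  structure(list(image = ct_image(hu, patient_id = patient,
                                  slice_index = (as.integer(index) - 1L) %% spec$slices_per_patient),
                 mask = mask, has_lesion = has_lesion, patient_id = patient,
                 lesion_area = sum(mask)),
            class = "phantom_sample")
}

#' Generate a phantom dataset on disk
#'
#' Writes one NIfTI image (or DICOM slice) and one PNG mask per sample, plus
#' a CSV manifest with per-sample lesion flags and patient-style grouping
#' ids. Outputs are standard formats readable by [read_nifti_volume()] /
#' [read_dicom_slice()] / [read_mask_png()].
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @param format `"nifti"` or `"dicom"` for the images.
#' @return Tibble manifest: `index`, `patient_id`, `has_lesion`,
#'   `lesion_area`, `image`, `mask` (paths).
#' @export
generate_dataset <- function(spec, out_dir, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  rows <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    s <- generate_sample(spec, i)
    img_path <- file.path(out_dir, sprintf("sample_%04d.%s", i,
                                           if (format == "nifti") "nii.gz" else "dcm"))
    if (format == "nifti") {
      write_nifti_volume(s$image$pixels, img_path)
    } else {
      write_dicom_slice(s$image, img_path)
    }
    mask_path <- file.path(out_dir, sprintf("sample_%04d_mask.png", i))
    write_mask_png(s$mask, mask_path)
    rows[[i]] <- tibble::tibble(index = i, patient_id = s$patient_id,
                                has_lesion = s$has_lesion, lesion_area = s$lesion_area,
                                image = img_path, mask = mask_path)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Phantom tensors ready for training
#'
#' Generates samples in memory, applies a Hounsfield window and resizes to
#' the model grid; masks are resized with nearest-neighbor.
#'
#' @param spec A [phantom_spec()].
#' @param indices Sample indices (default all of `spec$n_samples`).
#' @param window A [window_spec()]; the default lung window keeps all three
#'   HU anchors in distinct normalized bands.
#' @param side Model input side (divisible by 32).
#' @return `list(images =, masks =)` of `(side, side, N)` arrays.
#' @export
phantom_tensors <- function(spec, indices = seq_len(spec$n_samples),
                            window = lung_window(), side = 64L) {
  N <- length(indices)
  images <- array(0, c(side, side, N))
  masks <- array(0L, c(side, side, N))
  for (j in seq_along(indices)) {
    s <- generate_sample(spec, indices[j])
    images[, , j] <- resize_to_model(apply_window(s$image, window), side)
    masks[, , j] <- resize_mask(s$mask, side)
  }
  list(images = images, masks = masks)
}

#' Plot a phantom sample
#'
#' @param object A [generate_sample()] result.
#' @param window A [window_spec()] used for display.
#' @param ... Unused.
#' @return A ggplot showing the windowed image with the lesion outline.
#' @method autoplot phantom_sample
#' @export
autoplot.phantom_sample <- function(object, window = lung_window(), ...) {
  img <- apply_window(object$image, window)
  df <- data.frame(row = rep(seq_len(nrow(img)), times = ncol(img)),
                   col = rep(seq_len(ncol(img)), each = nrow(img)),
                   value = as.vector(img),
                   lesion = as.vector(object$mask) == 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = df[df$lesion, ], color = "red", size = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "intensity", title = "CT phantom (windowed)")
}
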