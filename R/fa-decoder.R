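# Feature-alignment decoder: feature maps become latent codes at continuous
# 2-D coordinates; every query coordinate is predicted by a shared MLP over
# the nearest code at each pyramid level plus position-encoded offsets.
#
# Global coordinate frame: the unit square [0,1]^2 with the pixel-center
# convention. The code at (row r, column c) of an H x W level (1-based) sits
# at ((r - 0.5)/H, (c - 0.5)/W). The same frame is shared by all levels and
# by query grids, which makes cross-level offsets well defined.

#' Pixel-center coordinates along one axis
#'
#' @param n Number of cells.
#' @return Numeric vector `((1:n) - 0.5) / n` in (0, 1).
#' @export
pixel_centers <- function(n) (seq_len(n) - 0.5) / n

#' Latent grid for one pyramid level
#'
#' Wraps one level's latent codes with their continuous coordinates.
#'
#' @param codes `H x W x C` array of latent codes.
#' @param level Level index (1..5).
#' @return Object of class `latent_grid` with fields `codes`, `level`,
#'   `row_coords`, `col_coords` (pixel centers in the global frame).
#' @export
latent_grid <- function(codes, level = 1L) {
  if (length(dim(codes)) != 3L) stop("codes must be an H x W x C array", call. = FALSE)
  d <- dim(codes)
  structure(list(codes = codes, level = as.integer(level),
                 row_coords = pixel_centers(d[1]), col_coords = pixel_centers(d[2])),
            class = "latent_grid")
}

#' Project a feature pyramid to latent grids
#'
#' Maps each pyramid level through its own (learned) 1x1 convolution to a
#' common latent width and attaches pixel-center coordinates.
#'
#' @param pyr A `feature_pyramid` from [encode()].
#' @param latent_width Common channel count C of the latent codes.
#' @param proj Optional list of five projections, each `list(W, b)` with `W`
#'   of shape `(C_i, latent_width)`; when omitted, weights are initialized
#'   from `seed`.
#' @param seed Seed used when `proj` is missing.
#' @return List of five [latent_grid()] objects.
#' @export
project_to_latents <- function(pyr, latent_width = 64L, proj = NULL, seed = 1L) {
  if (length(pyr) != 5L) stop("expected a 5-level pyramid, got ", length(pyr), " levels", call. = FALSE)
  if (is.null(proj)) {
    set.seed(as.integer(seed))
    proj <- lapply(pyr, function(f) {
      list(W = matrix(stats::rnorm(f$channels * latent_width, sd = sqrt(2 / f$channels)),
                      f$channels, latent_width),
           b = numeric(latent_width))
    })
  }
  lapply(1:5, function(i) {
    v <- pyr[[i]]$values
    d <- dim(v)
    dim(v) <- c(d[1] * d[2], d[3])
    z <- v %*% proj[[i]]$W + rep(proj[[i]]$b, each = d[1] * d[2])
    dim(z) <- c(d[1], d[2], ncol(proj[[i]]$W))
    latent_grid(z, level = i)
  })
}

# nearest cell index along one axis for query coordinate(s) q in [0,1]:
# ties (q exactly on a cell boundary) break toward the smaller index
.nearest_axis <- function(q, n) {
  pmin(pmax(ceiling(q * n) - 1L, 0L), n - 1L) + 1L   # 1-based
}

#' Nearest latent code to a query coordinate
#'
#' Finds the code whose coordinate minimizes Euclidean distance to `x_q`;
#' equidistant candidates resolve to the smallest row, then smallest column.
#'
#' @param grid A [latent_grid()].
#' @param x_q Numeric length-2 query coordinate `(row, col)` in `[0, 1]^2`.
#' @return List with `z_star` (length-C code), `x_star` (its coordinate),
#'   `delta` (`x_q - x_star`) and `index` (row, col, 1-based).
#' @export
nearest_latent <- function(grid, x_q) {
  if (any(x_q < 0) || any(x_q > 1)) stop("x_q must lie in [0,1]^2", call. = FALSE)
  d <- dim(grid$codes)
  r <- .nearest_axis(x_q[1], d[1])
  cc <- .nearest_axis(x_q[2], d[2])
  x_star <- c(grid$row_coords[r], grid$col_coords[cc])
  list(z_star = grid$codes[r, cc, ], x_star = x_star,
       delta = x_q - x_star, index = c(r, cc))
}

#' Sinusoidal position-encoding specification
#'
#' Frequencies default to `omega_l = 2 * e^l` for `l = 1..L`; both the number
#' of bands and the base are configurable (`base = 2` recovers the common
#' power-of-two ladder).
#'
#' @param L Number of frequency bands (>= 1).
#' @param base Base of the geometric frequency ladder (default `exp(1)`).
#' @param scale Multiplier of the ladder (default 2).
#' @return Object of class `pe_spec` with fields `L` and `omega`.
#' @export
pe_spec <- function(L = 8L, base = exp(1), scale = 2) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  # exp(l * log(base)) rather than base^l so the natural-base default gives
  # exactly exp(l); sin() of the large upper-band arguments would otherwise
  # amplify a one-ulp difference in omega
  omega <- scale * exp(seq_len(L) * log(base))
  if (any(diff(omega) <= 0)) stop("frequencies must be strictly increasing", call. = FALSE)
  structure(list(L = L, omega = omega), class = "pe_spec")
}

#' Position-encode a relative offset
#'
#' For each of the two offset components `u`, emits
#' `(sin(omega_1 u), cos(omega_1 u), ..., sin(omega_L u), cos(omega_L u))`;
#' the full encoding is the row-component block followed by the
#' column-component block, length `4 L`, every entry in `[-1, 1]`.
#'
#' @param delta Numeric length-2 offset, or an `n x 2` matrix of offsets.
#' @param spec A [pe_spec()].
#' @return Length-`4L` vector, or an `n x 4L` matrix for matrix input.
#' @export
position_encode <- function(delta, spec = pe_spec()) {
  one <- is.null(dim(delta))
  if (one) delta <- matrix(delta, 1L, 2L)
  if (ncol(delta) != 2L) stop("delta must have 2 components", call. = FALSE)
  n <- nrow(delta)
  out <- matrix(0, n, 4L * spec$L)
  for (comp in 1:2) {
    arg <- outer(delta[, comp], spec$omega)          # n x L
    block <- matrix(0, n, 2L * spec$L)
    block[, seq(1L, 2L * spec$L, 2L)] <- sin(arg)
    block[, seq(2L, 2L * spec$L, 2L)] <- cos(arg)
    out[, (comp - 1L) * 2L * spec$L + seq_len(2L * spec$L)] <- block
  }
  if (one) out[1, ] else out
}

#' Decoder MLP configuration
#'
#' The read-out maps the concatenation over the five levels of
#' `(z_i*, psi(delta x_i), delta x_i)` to class logits, so its input width is
#' `5 * (C + 4L + 2)`.
#'
#' @param latent_width Latent channel count C.
#' @param pe A [pe_spec()].
#' @param hidden Integer vector of hidden-layer widths.
#' @param num_classes Number of output classes (>= 2).
#' @return Object of class `decoder_mlp_config`.
#' @export
decoder_mlp_config <- function(latent_width = 64L, pe = pe_spec(),
                               hidden = c(256L, 256L), num_classes = 2L) {
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  structure(list(latent_width = as.integer(latent_width), pe = pe,
                 hidden = as.integer(hidden), num_classes = as.integer(num_classes),
                 input_width = 5L * (as.integer(latent_width) + 4L * pe$L + 2L)),
            class = "decoder_mlp_config")
}

.mlp_init <- function(cfg) {
  widths <- c(cfg$input_width, cfg$hidden, cfg$num_classes)
  P <- list()
  for (i in seq_len(length(widths) - 1L)) {
    sd <- if (i == length(widths) - 1L) 0.01 else sqrt(2 / widths[i])
    P <- c(P, .with_prefix(.dense_init(widths[i], widths[i + 1L], sd = sd), paste0("l", i)))
  }
  P
}

.mlp_fwd <- function(X, P, prefix, n_layers, keep_cache = FALSE) {
  acts <- if (keep_cache) list(X) else NULL
  h <- X
  for (i in seq_len(n_layers)) {
    h <- .dense_fwd(h, P, sprintf("%s.l%d", prefix, i))
    if (i < n_layers) h <- .relu_fwd(h)
    if (keep_cache) acts[[i + 1L]] <- h
  }
  list(out = h, acts = acts)
}

.mlp_bwd <- function(dout, acts, P, prefix, n_layers, gr) {
  dh <- dout
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) dh <- dh * (acts[[i + 1L]] > 0)
    dh <- .dense_bwd(dh, acts[[i]], P, sprintf("%s.l%d", prefix, i), gr)
  }
  dh
}

# Build the decoder input matrix for a set of query points.
# grids: list of 5 latent_grid. queries: n x 2 matrix in [0,1]^2.
# Returns X (n x 5*(C+4L+2)), per-level gather indices, and column spans.
.fa_build_inputs <- function(grids, queries, pe) {
  n <- nrow(queries)
  C <- dim(grids[[1]]$codes)[3]
  span_z <- C
  span_pe <- 4L * pe$L
  width <- 5L * (span_z + span_pe + 2L)
  X <- matrix(0, n, width)
  idx <- vector("list", 5L)
  col0 <- 0L
  for (i in 1:5) {
    d <- dim(grids[[i]]$codes)
    r <- .nearest_axis(queries[, 1], d[1])
    cc <- .nearest_axis(queries[, 2], d[2])
    lin <- r + (cc - 1L) * d[1]
    idx[[i]] <- lin
    zm <- grids[[i]]$codes
    dim(zm) <- c(d[1] * d[2], d[3])
    X[, col0 + seq_len(span_z)] <- zm[lin, , drop = FALSE]
    delta <- cbind(queries[, 1] - grids[[i]]$row_coords[r],
                   queries[, 2] - grids[[i]]$col_coords[cc])
    X[, col0 + span_z + seq_len(span_pe)] <- position_encode(delta, pe)
    X[, col0 + span_z + span_pe + 1:2] <- delta
    col0 <- col0 + span_z + span_pe + 2L
  }
  list(X = X, idx = idx, span = c(z = span_z, pe = span_pe), width = width)
}

#' Decode class logits at one query coordinate
#'
#' Concatenates, in level order 1..5, the nearest latent code, the
#' position-encoded offset and the raw offset, and applies the read-out.
#'
#' @param x_q Length-2 query coordinate in `[0, 1]^2`.
#' @param grids List of five [latent_grid()] objects.
#' @param spec A [pe_spec()].
#' @param mlp Either a function taking the `n x input_width` matrix and
#'   returning an `n x num_classes` matrix (useful for stub read-outs), or a
#'   fitted decoder parameter list as stored in an `efanet_model`.
#' @return Numeric vector of class logits.
#' @export
decode_point <- function(x_q, grids, spec = pe_spec(), mlp) {
  if (any(x_q < 0) || any(x_q > 1)) stop("x_q must lie in [0,1]^2", call. = FALSE)
  inp <- .fa_build_inputs(grids, matrix(x_q, 1L, 2L), spec)
  drop(.apply_mlp(mlp, inp$X))
}

.apply_mlp <- function(mlp, X) {
  if (is.function(mlp)) return(mlp(X))
  # parameter list form: names l1.W, l1.b, ...
  n_layers <- length(grep("^l[0-9]+\\.W$", names(mlp)))
  P <- .with_prefix(mlp, "mlp")
  if (ncol(X) != nrow(P[["mlp.l1.W"]])) {
    stop("decoder input width ", ncol(X), " does not match MLP (", nrow(P[["mlp.l1.W"]]), ")", call. = FALSE)
  }
  .mlp_fwd(X, P, "mlp", n_layers)$out
}

#' Decode a full logit grid
#'
#' Evaluates [decode_point()] at every pixel center of `target_shape` (or at
#' explicit `queries`). Because the latent field is continuous in the query
#' coordinate, any target resolution is valid for a fixed set of latent
#' grids -- no retraining or upsampling is involved.
#'
#' @param grids List of five [latent_grid()] objects.
#' @param spec A [pe_spec()].
#' @param mlp Read-out, as in [decode_point()].
#' @param target_shape Integer `(H_q, W_q)`.
#' @param queries Optional explicit `n x 2` coordinate matrix overriding
#'   `target_shape`.
#' @param chunk Queries are processed in blocks of this many rows to bound
#'   memory at large output resolutions.
#' @return `H_q x W_q x num_classes` logit array (or `n x num_classes` matrix
#'   when `queries` is given).
#' @export
decode_grid <- function(grids, spec = pe_spec(), mlp, target_shape = c(256L, 256L),
                        queries = NULL, chunk = 65536L) {
  grid_out <- is.null(queries)
  if (grid_out) {
    H <- as.integer(target_shape[1]); W <- as.integer(target_shape[2])
    if (H < 1L || W < 1L) stop("target_shape must be >= 1", call. = FALSE)
    queries <- cbind(rep(pixel_centers(H), times = W),
                     rep(pixel_centers(W), each = H))
  }
  n <- nrow(queries)
  out <- NULL
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    inp <- .fa_build_inputs(grids, queries[lo:hi, , drop = FALSE], spec)
    block <- .apply_mlp(mlp, inp$X)
    if (is.null(out)) out <- matrix(0, n, ncol(block))
    out[lo:hi, ] <- block
  }
  if (grid_out) {
    dim(out) <- c(H, W, ncol(out))
  }
  out
}

#' Convert logits to a binary segmentation mask
#'
#' Per-pixel argmax over classes; exact ties resolve to the first class
#' (class 0, background).
#'
#' @param logits `H x W x num_classes` array or `n x num_classes` matrix.
#' @return Integer matrix (or vector) of class labels starting at 0; for two
#'   classes this is a binary mask.
#' @export
predict_mask <- function(logits) {
  d <- dim(logits)
  if (length(d) == 3L) {
    m <- logits
    dim(m) <- c(d[1] * d[2], d[3])
    lab <- max.col(m, ties.method = "first") - 1L
    matrix(lab, d[1], d[2])
  } else {
    max.col(logits, ties.method = "first") - 1L
  }
}
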