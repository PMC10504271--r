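# Full segmentation model: encoder taps -> per-level 1x1 latent projections
# -> feature-alignment read-out MLP. Parameters for all parts live in one
# flat named list ("enc.*", "dec.proj<i>.*", "dec.mlp.l<i>.*") so a single
# Adam state covers the whole network.

#' Construct a feature-alignment segmentation model
#'
#' @param encoder An [encoder_config()] or preset name (`"tiny"`, `"b5like"`).
#' @param latent_width Latent channel count C shared by all levels.
#' @param pe A [pe_spec()] for the offset position encoding.
#' @param hidden Hidden-layer widths of the read-out MLP.
#' @param num_classes Number of classes (2 = background/pneumothorax).
#' @param input_side Native input resolution (divisible by 32); the default
#'   output grid matches it, but any resolution can be decoded.
#' @param seed Integer seed governing all weight initialization.
#' @return Object of class `efanet_model`.
#' @examples
#' m <- efanet_model("tiny", latent_width = 16, hidden = c(32, 32), input_side = 64)
#' count_parameters(m)
#' @export
efanet_model <- function(encoder = "tiny", latent_width = 64L, pe = pe_spec(),
                         hidden = c(256L, 256L), num_classes = 2L,
                         input_side = 256L, seed = 1L) {
  if (is.character(encoder)) encoder <- encoder_config(encoder)
  if (input_side %% 32L != 0L) stop("input_side must be divisible by 32", call. = FALSE)
  enc <- build_encoder(encoder, seed = seed)
  mlp_cfg <- decoder_mlp_config(latent_width, pe, hidden, num_classes)
  set.seed(as.integer(seed) + 1L)
  tap_channels <- encoder$stage_channels[c(1, 3, 4, 5, 6)]
  P <- .with_prefix(enc$params, "enc")
  for (i in 1:5) {
    P <- c(P, .with_prefix(.conv1x1_init(tap_channels[i], as.integer(latent_width), bias = TRUE),
                           sprintf("dec.proj%d", i)))
  }
  P <- c(P, .with_prefix(.mlp_init(mlp_cfg), "dec.mlp"))
  state <- enc$bn_state
  names(state) <- paste0("enc.", names(state))
  structure(list(
    encoder_config = encoder,
    mlp_config = mlp_cfg,
    latent_width = as.integer(latent_width),
    pe = pe,
    num_classes = as.integer(num_classes),
    input_side = as.integer(input_side),
    seed = as.integer(seed),
    plan = .stage_plan(encoder),
    tap_channels = tap_channels,
    params = P,
    bn_state = state
  ), class = "efanet_model")
}

#' @export
print.efanet_model <- function(x, ...) {
  cat("<efanet_model>\n")
  cat("  encoder:", x$encoder_config$preset,
      " latent width:", x$latent_width,
      " PE bands:", x$pe$L, "\n")
  cat("  read-out:", paste(c(x$mlp_config$input_width, x$mlp_config$hidden,
                             x$num_classes), collapse = " -> "), "\n")
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}

.n_mlp_layers <- function(model) length(model$mlp_config$hidden) + 1L

# forward through encoder + projections for a batch x (H, W, N, 1)
.latents_fwd <- function(model, x, train, keep_cache = train, state = model$bn_state) {
  er <- .encoder_fwd(model$params, model$plan, model$encoder_config, state, x,
                     train = train, keep_cache = keep_cache, prefix = "enc.")
  latents <- vector("list", 5L)
  for (i in 1:5) {
    latents[[i]] <- .conv1x1_fwd(er$taps[[i]], model$params, sprintf("dec.proj%d", i))
  }
  list(latents = latents, taps = er$taps, state = er$state, enc_caches = er$caches)
}

# Assemble the decoder input matrix for a batch.
# latents: list of (Hi, Wi, N, C); queries: either one nq x 2 matrix shared
# by the whole batch, or a list of N such matrices (per-image query sets, as
# used by class-balanced sampling). Rows of X are ordered query-fastest,
# then batch; with shared queries the PE/offset columns are reused across
# the batch.
.fa_batch_inputs <- function(model, latents, queries) {
  N <- dim(latents[[1]])[3]
  per_image <- is.list(queries)
  nq <- if (per_image) nrow(queries[[1]]) else nrow(queries)
  C <- model$latent_width
  span_pe <- 4L * model$pe$L
  width <- model$mlp_config$input_width
  X <- matrix(0, nq * N, width)
  idx <- vector("list", 5L)
  col0 <- 0L
  for (i in 1:5) {
    d <- dim(latents[[i]])
    zm <- latents[[i]]
    dim(zm) <- c(d[1] * d[2], d[3] * d[4])
    if (per_image) {
      lin_n <- vector("list", N)
      for (n in seq_len(N)) {
        q <- queries[[n]]
        r <- .nearest_axis(q[, 1], d[1])
        cc <- .nearest_axis(q[, 2], d[2])
        lin <- r + (cc - 1L) * d[1]
        lin_n[[n]] <- lin
        rows <- (n - 1L) * nq + seq_len(nq)
        # columns of zm are (n, c) pairs with n fastest
        X[rows, col0 + seq_len(C)] <- zm[lin, n + (seq_len(C) - 1L) * N, drop = FALSE]
        delta <- cbind(q[, 1] - pixel_centers(d[1])[r],
                       q[, 2] - pixel_centers(d[2])[cc])
        X[rows, col0 + C + seq_len(span_pe + 2L)] <- cbind(position_encode(delta, model$pe), delta)
      }
      idx[[i]] <- lin_n
    } else {
      r <- .nearest_axis(queries[, 1], d[1])
      cc <- .nearest_axis(queries[, 2], d[2])
      lin <- r + (cc - 1L) * d[1]
      idx[[i]] <- lin
      zg <- zm[lin, , drop = FALSE]         # (nq, N*C)
      dim(zg) <- c(nq * N, C)
      X[, col0 + seq_len(C)] <- zg
      delta <- cbind(queries[, 1] - pixel_centers(d[1])[r],
                     queries[, 2] - pixel_centers(d[2])[cc])
      pe_block <- cbind(position_encode(delta, model$pe), delta)
      X[, col0 + C + seq_len(span_pe + 2L)] <- pe_block[rep(seq_len(nq), times = N), , drop = FALSE]
    }
    col0 <- col0 + C + span_pe + 2L
  }
  list(X = X, idx = idx, nq = nq, N = N, per_image = per_image)
}

# full training-mode forward: returns logits (nq*N, K) and all caches
.model_fwd <- function(model, x, queries, train) {
  lf <- .latents_fwd(model, x, train = train, keep_cache = train)
  inp <- .fa_batch_inputs(model, lf$latents, queries)
  mr <- .mlp_fwd(inp$X, model$params, "dec.mlp", .n_mlp_layers(model), keep_cache = train)
  list(logits = mr$out, inp = inp, mlp_acts = mr$acts, lf = lf)
}

# backward from dlogits; accumulates parameter grads into gr
.model_bwd <- function(model, fwd, dlogits, gr) {
  dX <- .mlp_bwd(dlogits, fwd$mlp_acts, model$params, "dec.mlp", .n_mlp_layers(model), gr)
  inp <- fwd$inp
  C <- model$latent_width
  span <- C + 4L * model$pe$L + 2L
  dtaps <- vector("list", 5L)
  for (i in 1:5) {
    lat <- fwd$lf$latents[[i]]
    d <- dim(lat)
    dz <- dX[, (i - 1L) * span + seq_len(C), drop = FALSE]   # (nq*N, C)
    dlat <- matrix(0, d[1] * d[2], inp$N * C)
    if (inp$per_image) {
      for (n in seq_len(inp$N)) {
        rows <- (n - 1L) * inp$nq + seq_len(inp$nq)
        rs <- rowsum(dz[rows, , drop = FALSE], group = inp$idx[[i]][[n]])
        cols <- n + (seq_len(C) - 1L) * inp$N
        dlat[as.integer(rownames(rs)), cols] <- dlat[as.integer(rownames(rs)), cols, drop = FALSE] + rs
      }
    } else {
      dim(dz) <- c(inp$nq, inp$N * C)
      rs <- rowsum(dz, group = inp$idx[[i]])
      dlat[as.integer(rownames(rs)), ] <- rs
    }
    dim(dlat) <- d
    dtaps[[i]] <- .conv1x1_bwd(dlat, fwd$lf$taps[[i]], model$params,
                               sprintf("dec.proj%d", i), gr)
  }
  .encoder_bwd(model$params, model$plan, fwd$lf$enc_caches, dtaps, gr, prefix = "enc.")
  invisible(NULL)
}

#' Predict a segmentation mask for one image
#'
#' Runs the encoder once, then decodes class logits at the pixel centers of
#' an arbitrary output grid (the feature field is continuous, so the output
#' resolution is independent of the input resolution).
#'
#' @param object A fitted or freshly built `efanet_model`.
#' @param img Numeric matrix, normalized image with sides divisible by 32.
#' @param out_shape Output grid `(H, W)`; defaults to the input shape.
#' @param type `"mask"` for the argmax label matrix, `"logits"` for the
#'   `H x W x num_classes` array.
#' @param queries Optional explicit `n x 2` query coordinates (overrides
#'   `out_shape`; returns a matrix of logits or a label vector).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.efanet_model <- function(object, img, out_shape = NULL, type = c("mask", "logits"),
                                 queries = NULL, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(img))
  if (is.null(out_shape)) out_shape <- dim(img)
  x <- array(img, c(dim(img), 1L, 1L))
  lf <- .latents_fwd(object, x, train = FALSE, keep_cache = FALSE)
  grids <- lapply(1:5, function(i) {
    v <- lf$latents[[i]]
    d <- dim(v)
    dim(v) <- c(d[1], d[2], d[4])
    latent_grid(v, level = i)
  })
  mlp_params <- .strip_prefix(object$params, "dec.mlp.")
  logits <- decode_grid(grids, object$pe, mlp_params,
                        target_shape = out_shape, queries = queries)
  if (type == "logits") logits else predict_mask(logits)
}

.strip_prefix <- function(P, prefix) {
  keep <- startsWith(names(P), prefix)
  out <- P[keep]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

#' Latent grids of a model for one image
#'
#' Convenience accessor used to inspect the continuous feature field:
#' encodes the image and applies the model's latent projections.
#'
#' @param model An `efanet_model`.
#' @param img Normalized image matrix.
#' @return List of five [latent_grid()] objects.
#' @export
model_latents <- function(model, img) {
  x <- array(img, c(dim(img), 1L, 1L))
  lf <- .latents_fwd(model, x, train = FALSE, keep_cache = FALSE)
  lapply(1:5, function(i) {
    v <- lf$latents[[i]]
    d <- dim(v)
    dim(v) <- c(d[1], d[2], d[4])
    latent_grid(v, level = i)
  })
}

#' Count trainable parameters
#'
#' Counts every entry of every weight, bias and batch-norm affine parameter;
#' batch-norm running statistics are not parameters.
#'
#' @param model An `efanet_model` (or an encoder from [build_encoder()]).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  P <- if (inherits(model, "efanet_encoder")) model$params else model$params
  sum(vapply(P, length, numeric(1)))
}

#' Estimate multiply-accumulate operations
#'
#' Counting rule: convolutions and dense (linear) layers only, one
#' multiply-accumulate counted as one operation (the convention of common
#' network profilers that report "FLOPs"); normalization, activations and
#' pooling are excluded. The decoder MLP cost is counted once per query
#' pixel of the output grid.
#'
#' @param model An `efanet_model`.
#' @param input_side Input resolution (default the model's native side).
#' @param out_shape Output query grid (default `input_side` squared).
#' @return List with components `conv` (encoder + latent-projection
#'   convolutions), `se_dense` (squeeze-excitation layers), `mlp` (read-out
#'   over all queries) and `total`, in multiply-accumulates, plus
#'   `total_gmacs`.
#' @export
estimate_flops <- function(model, input_side = model$input_side, out_shape = NULL) {
  side <- as.integer(input_side)
  if (is.null(out_shape)) out_shape <- c(side, side)
  cfg <- model$encoder_config
  ch <- cfg$stage_channels
  conv <- 0; se <- 0
  s_stem <- side / 2
  conv <- conv + 9 * 1 * ch[1] * s_stem^2
  res <- s_stem
  for (s in 1:5) {
    for (b in seq_along(model$plan[[s]])) {
      sp <- model$plan[[s]][[b]]
      mid <- sp$in_c * cfg$expansion_ratio
      se_c <- max(1L, as.integer(round(sp$in_c * cfg$se_ratio)))
      rin <- res
      rout <- if (sp$stride == 2L) res / 2 else res
      if (cfg$expansion_ratio > 1L) conv <- conv + sp$in_c * mid * rin^2
      conv <- conv + 9 * mid * rout^2
      se <- se + mid * se_c + se_c * mid
      conv <- conv + mid * sp$out_c * rout^2
      res <- rout
    }
  }
  strides <- c(2L, 4L, 8L, 16L, 32L)
  for (i in 1:5) {
    conv <- conv + model$tap_channels[i] * model$latent_width * (side / strides[i])^2
  }
  widths <- c(model$mlp_config$input_width, model$mlp_config$hidden, model$num_classes)
  per_query <- sum(widths[-length(widths)] * widths[-1])
  mlp <- per_query * prod(out_shape)
  total <- conv + se + mlp
  list(conv = conv, se_dense = se, mlp = mlp, total = total,
       total_gmacs = total / 1e9)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing container holding the configuration,
#' every parameter array and the batch-norm running statistics; save followed
#' by load reproduces predictions bit-exactly.
#'
#' @param model An `efanet_model` (or `efanet_fit`, whose best model is saved).
#' @param path File path.
#' @return `load_checkpoint` returns the `efanet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "efanet_fit")) model <- model$model
  stopifnot(inherits(model, "efanet_model"))
  obj <- list(format = "efanet-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "efanet-checkpoint")) {
    stop("not an efanet checkpoint: ", path, call. = FALSE)
  }
  obj$model
}
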