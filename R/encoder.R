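#' Encoder configuration
#'
#' Describes the multi-scale convolutional encoder: a 3x3 stride-2 stem
#' followed by five MBConv stages. The first stage keeps the stem resolution;
#' stages 2-5 each open with a stride-2 block, so the pyramid taps (stem
#' output plus the outputs of stages 2-5) sit at strides 2, 4, 8, 16 and 32
#' relative to the input.
#'
#' @param preset `"tiny"` (a small configuration suited to CPU training and
#'   tests, well under half a million encoder parameters) or `"b5like"`
#'   (EfficientNet-B5-style depth and width). Individual fields override the
#'   preset.
#' @param stage_channels Six integers: stem channels then output channels of
#'   the five stages. All must be >= 4.
#' @param stage_depths Five integers >= 1: MBConv blocks per stage.
#' @param expansion_ratio Integer >= 1, MBConv expansion factor.
#' @param se_ratio Squeeze-and-excitation reduction ratio in (0, 1].
#' @return An object of class `encoder_config`.
#' @examples
#' encoder_config("tiny")
#' @export
encoder_config <- function(preset = c("tiny", "b5like"),
                           stage_channels = NULL,
                           stage_depths = NULL,
                           expansion_ratio = NULL,
                           se_ratio = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(stage_channels = c(8L, 8L, 16L, 24L, 32L, 48L),
                stage_depths = c(1L, 1L, 1L, 1L, 1L),
                expansion_ratio = 2L, se_ratio = 0.25),
    b5like = list(stage_channels = c(48L, 24L, 40L, 64L, 176L, 512L),
                  stage_depths = c(3L, 5L, 5L, 9L, 12L),
                  expansion_ratio = 6L, se_ratio = 0.25))
  if (!is.null(stage_channels)) cfg$stage_channels <- as.integer(stage_channels)
  if (!is.null(stage_depths)) cfg$stage_depths <- as.integer(stage_depths)
  if (!is.null(expansion_ratio)) cfg$expansion_ratio <- as.integer(expansion_ratio)
  if (!is.null(se_ratio)) cfg$se_ratio <- se_ratio
  if (length(cfg$stage_channels) != 6L || any(cfg$stage_channels < 4L)) {
    stop("stage_channels must be 6 integers >= 4", call. = FALSE)
  }
  if (length(cfg$stage_depths) != 5L || any(cfg$stage_depths < 1L)) {
    stop("stage_depths must be 5 integers >= 1", call. = FALSE)
  }
  if (cfg$expansion_ratio < 1L) stop("expansion_ratio must be >= 1", call. = FALSE)
  if (cfg$se_ratio <= 0 || cfg$se_ratio > 1) stop("se_ratio must be in (0, 1]", call. = FALSE)
  cfg$preset <- preset
  structure(cfg, class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("<encoder_config> preset:", x$preset, "\n")
  cat("  stem + stage channels:", paste(x$stage_channels, collapse = "/"), "\n")
  cat("  stage depths:", paste(x$stage_depths, collapse = "/"),
      " expansion:", x$expansion_ratio, " se_ratio:", x$se_ratio, "\n")
  invisible(x)
}

# per-block channel bookkeeping for one stage
.stage_plan <- function(cfg) {
  ch <- cfg$stage_channels
  plan <- list()
  for (s in 1:5) {
    cin0 <- if (s == 1) ch[1] else ch[s]
    blocks <- list()
    for (b in seq_len(cfg$stage_depths[s])) {
      blocks[[b]] <- list(
        in_c = if (b == 1) cin0 else ch[s + 1],
        out_c = ch[s + 1],
        stride = if (b == 1 && s > 1) 2L else 1L)
    }
    plan[[s]] <- blocks
  }
  plan
}

.mbconv_init <- function(in_c, out_c, expansion_ratio, se_ratio) {
  mid <- in_c * expansion_ratio
  se_c <- max(1L, as.integer(round(in_c * se_ratio)))
  p <- list()
  if (expansion_ratio > 1L) {
    p <- c(p, .with_prefix(.conv1x1_init(in_c, mid), "exp"),
           .with_prefix(.bn_init(mid), "bn1"))
  }
  p <- c(p,
    .with_prefix(.dwconv3x3_init(mid), "dw"),
    .with_prefix(.bn_init(mid), "bn2"),
    .with_prefix(.dense_init(mid, se_c), "se1"),
    .with_prefix(.dense_init(se_c, mid), "se2"),
    .with_prefix(.conv1x1_init(mid, out_c), "proj"),
    .with_prefix(.bn_init(out_c), "bn3"))
  p
}

.mbconv_bn_state <- function(in_c, out_c, expansion_ratio, prefix) {
  mid <- in_c * expansion_ratio
  st <- list()
  if (expansion_ratio > 1L) st[[paste0(prefix, ".bn1")]] <- .bn_state_init(mid)
  st[[paste0(prefix, ".bn2")]] <- .bn_state_init(mid)
  st[[paste0(prefix, ".bn3")]] <- .bn_state_init(out_c)
  st
}

# forward through one MBConv block; returns output, updated bn state and a
# cache sufficient for the backward pass
.mbconv_fwd <- function(x, P, prefix, spec, state, train) {
  in_c <- spec$in_c; out_c <- spec$out_c; stride <- spec$stride
  expand <- !is.null(P[[paste0(prefix, ".exp.W")]])
  cache <- list(x = x, spec = spec, expand = expand)

  if (expand) {
    h0 <- .conv1x1_fwd(x, P, paste0(prefix, ".exp"))
    b1 <- .bn_fwd(h0, P, paste0(prefix, ".bn1"), state, train)
    state <- b1$state
    a1 <- .swish_fwd(b1$out)
    cache$h0 <- h0; cache$bn1 <- b1$cache; cache$bn1_in <- b1$out; cache$sw1 <- a1
    h1 <- a1$out
  } else {
    h1 <- x
  }

  h2 <- .dwconv3x3_fwd(h1, P, paste0(prefix, ".dw"), stride)
  b2 <- .bn_fwd(h2, P, paste0(prefix, ".bn2"), state, train)
  state <- b2$state
  a2 <- .swish_fwd(b2$out)
  cache$h1 <- h1; cache$bn2 <- b2$cache; cache$bn2_in <- b2$out; cache$sw2 <- a2
  h3 <- a2$out

  # squeeze-and-excitation: global pool -> reduce -> swish -> expand -> sigmoid
  s <- .gap_fwd(h3)
  u <- .dense_fwd(s, P, paste0(prefix, ".se1"))
  au <- .swish_fwd(u)
  v <- .dense_fwd(au$out, P, paste0(prefix, ".se2"))
  g <- .sigmoid(v)
  d3 <- dim(h3)
  gate <- rep(as.vector(g), each = d3[1] * d3[2])
  h4 <- h3 * array(gate, d3)
  cache$h3 <- h3; cache$s <- s; cache$u <- u; cache$au <- au; cache$g <- g

  h5 <- .conv1x1_fwd(h4, P, paste0(prefix, ".proj"))
  b3 <- .bn_fwd(h5, P, paste0(prefix, ".bn3"), state, train)
  state <- b3$state
  cache$h4 <- h4; cache$h5 <- h5; cache$bn3 <- b3$cache
  out <- b3$out

  skip <- stride == 1L && in_c == out_c
  if (skip) out <- out + x
  cache$skip <- skip
  list(out = out, state = state, cache = cache)
}

.mbconv_bwd <- function(dout, P, prefix, cache, gr) {
  spec <- cache$spec
  dskip <- if (cache$skip) dout else 0

  dh5 <- .bn_bwd(dout, cache$bn3, P, paste0(prefix, ".bn3"), gr)
  dh4 <- .conv1x1_bwd(dh5, cache$h4, P, paste0(prefix, ".proj"), gr)

  h3 <- cache$h3
  d3 <- dim(h3)
  gate <- array(rep(as.vector(cache$g), each = d3[1] * d3[2]), d3)
  dh3_direct <- dh4 * gate
  dg_mat <- .gap_fwd(dh4 * h3) * (d3[1] * d3[2])   # sum over H, W per (n, c)
  dv <- dg_mat * cache$g * (1 - cache$g)
  dau <- .dense_bwd(dv, cache$au$out, P, paste0(prefix, ".se2"), gr)
  du <- .swish_bwd(dau, cache$au, cache$u)
  ds <- .dense_bwd(du, cache$s, P, paste0(prefix, ".se1"), gr)
  dh3 <- dh3_direct + .gap_bwd(ds, d3)

  db2 <- .swish_bwd(dh3, cache$sw2, cache$bn2_in)
  dh2 <- .bn_bwd(db2, cache$bn2, P, paste0(prefix, ".bn2"), gr)
  dh1 <- .dwconv3x3_bwd(dh2, cache$h1, P, paste0(prefix, ".dw"), spec$stride, gr)

  if (cache$expand) {
    db1 <- .swish_bwd(dh1, cache$sw1, cache$bn1_in)
    dh0 <- .bn_bwd(db1, cache$bn1, P, paste0(prefix, ".bn1"), gr)
    dx <- .conv1x1_bwd(dh0, cache$x, P, paste0(prefix, ".exp"), gr)
  } else {
    dx <- dh1
  }
  dx + dskip
}

#' Build an encoder
#'
#' Initializes all encoder weights (fan-out-scaled normal for convolutions,
#' unit-gamma/zero-beta batch norm) deterministically from `seed`.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `efanet_encoder` holding the configuration,
#'   the parameter list and the batch-norm running statistics.
#' @examples
#' enc <- build_encoder(encoder_config("tiny"), seed = 1)
#' @export
build_encoder <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "encoder_config")) stop("cfg must be an encoder_config", call. = FALSE)
  set.seed(as.integer(seed))
  ch <- cfg$stage_channels
  P <- c(.with_prefix(.conv3x3_init(1L, ch[1]), "stem.conv"),
         .with_prefix(.bn_init(ch[1]), "stem.bn"))
  state <- list(stem.bn = .bn_state_init(ch[1]))
  plan <- .stage_plan(cfg)
  for (s in 1:5) {
    for (b in seq_along(plan[[s]])) {
      sp <- plan[[s]][[b]]
      prefix <- sprintf("s%d.b%d", s, b)
      P <- c(P, .with_prefix(.mbconv_init(sp$in_c, sp$out_c, cfg$expansion_ratio, cfg$se_ratio), prefix))
      state <- c(state, .mbconv_bn_state(sp$in_c, sp$out_c, cfg$expansion_ratio, prefix))
    }
  }
  structure(list(config = cfg, params = P, bn_state = state, plan = plan),
            class = "efanet_encoder")
}

#' @export
print.efanet_encoder <- function(x, ...) {
  cat("<efanet_encoder> preset:", x$config$preset,
      " parameters:", sum(vapply(x$params, length, integer(1))), "\n")
  invisible(x)
}

# internal forward: x is (H, W, N, 1); returns taps (list of 5 (H,W,N,C)
# arrays), bn state and caches when train or keep_cache
.encoder_fwd <- function(P, plan, cfg, state, x, train = FALSE, keep_cache = train, prefix = "") {
  caches <- if (keep_cache) list() else NULL
  h0 <- .conv3x3_fwd(x, P, paste0(prefix, "stem.conv"), stride = 2L)
  b0 <- .bn_fwd(h0, P, paste0(prefix, "stem.bn"), state, train)
  state <- b0$state
  a0 <- .swish_fwd(b0$out)
  if (keep_cache) caches$stem <- list(x = x, h0 = h0, bn = b0$cache, bn_in = b0$out, sw = a0)
  h <- a0$out
  taps <- list()
  taps[[1]] <- h
  for (s in 1:5) {
    for (b in seq_along(plan[[s]])) {
      blk <- sprintf("%ss%d.b%d", prefix, s, b)
      r <- .mbconv_fwd(h, P, blk, plan[[s]][[b]], state, train)
      state <- r$state
      h <- r$out
      if (keep_cache) caches[[blk]] <- r$cache
    }
    if (s >= 2) taps[[s]] <- h
  }
  # taps: stem (stride 2) then stages 2..5 (strides 4, 8, 16, 32)
  list(taps = taps, state = state, caches = caches)
}

# backward: dtaps is a list of 5 gradients aligned with taps (NULL allowed)
.encoder_bwd <- function(P, plan, caches, dtaps, gr, prefix = "") {
  dh <- NULL
  add <- function(a, b) if (is.null(a)) b else a + b
  for (s in 5:1) {
    if (s >= 2 && !is.null(dtaps[[s]])) dh <- add(dh, dtaps[[s]])
    for (b in rev(seq_along(plan[[s]]))) {
      blk <- sprintf("%ss%d.b%d", prefix, s, b)
      dh <- .mbconv_bwd(dh, P, blk, caches[[blk]], gr)
    }
  }
  if (!is.null(dtaps[[1]])) dh <- add(dh, dtaps[[1]])
  cs <- caches$stem
  db <- .swish_bwd(dh, cs$sw, cs$bn_in)
  dh0 <- .bn_bwd(db, cs$bn, P, paste0(prefix, "stem.bn"), gr)
  .conv3x3_bwd(dh0, cs$x, P, paste0(prefix, "stem.conv"), 2L, gr)
}

#' Apply an MBConv block to a feature map
#'
#' One mobile inverted bottleneck convolution: 1x1 expansion, 3x3 depthwise
#' convolution (stride 1 or 2), squeeze-and-excitation channel gating, 1x1
#' projection, with a residual skip when stride is 1 and the channel count is
#' preserved. Batch statistics are computed from the given batch.
#'
#' @param x Feature map array `(H, W, C)` for a single sample or `(H, W, N, C)`.
#' @param in_c,out_c Input and output channel counts; `in_c` must match `x`.
#' @param stride 1 or 2.
#' @param expansion_ratio Expansion factor (integer >= 1).
#' @param se_ratio Squeeze-and-excitation reduction ratio in (0, 1].
#' @param params Optional parameter list (as produced internally); when
#'   omitted, weights are initialized from `seed`.
#' @param seed Seed for weight initialization when `params` is missing.
#' @return Feature map with the same layout as `x` (batch axis dropped if the
#'   input had none).
#' @export
mbconv_block <- function(x, in_c, out_c, stride = 1L, expansion_ratio = 2L,
                         se_ratio = 0.25, params = NULL, seed = 1L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
    squeeze <- TRUE
  }
  if (dim(x)[4] != in_c) stop("x has ", dim(x)[4], " channels, expected in_c = ", in_c, call. = FALSE)
  if (is.null(params)) {
    set.seed(as.integer(seed))
    params <- .mbconv_init(in_c, out_c, as.integer(expansion_ratio), se_ratio)
  }
  P <- .with_prefix(params, "blk")
  state <- .mbconv_bn_state(in_c, out_c, as.integer(expansion_ratio), "blk")
  spec <- list(in_c = in_c, out_c = out_c, stride = as.integer(stride))
  out <- .mbconv_fwd(x, P, "blk", spec, state, train = TRUE)$out
  if (squeeze) {
    d <- dim(out)
    dim(out) <- c(d[1], d[2], d[4])
  }
  out
}

#' Extract the five-level feature pyramid from an image
#'
#' Runs the encoder in inference mode on a normalized single-channel image
#' whose side is divisible by 32 and returns feature maps at strides 2, 4, 8,
#' 16 and 32 (taps after the stem and after stages 2-5): a 256x256 input
#' yields sides 128, 64, 32, 16 and 8.
#'
#' @param enc An encoder from [build_encoder()].
#' @param img Numeric matrix `(side, side)` with values typically in `[0, 1]`.
#' @return An object of class `feature_pyramid`: a list of five elements, each
#'   with `values` (`H x W x C` array), `level`, `stride` and `channels`.
#' @examples
#' enc <- build_encoder(encoder_config("tiny"), seed = 1)
#' pyr <- encode(enc, matrix(0.5, 64, 64))
#' vapply(pyr, function(f) f$stride, numeric(1))
#' @export
encode <- function(enc, img) {
  if (!inherits(enc, "efanet_encoder")) stop("enc must be an efanet_encoder", call. = FALSE)
  if (!is.matrix(img)) stop("img must be a 2-D matrix", call. = FALSE)
  side <- dim(img)
  if (side[1] %% 32L != 0L || side[2] %% 32L != 0L) {
    stop("image sides must be divisible by 32, got ", side[1], "x", side[2], call. = FALSE)
  }
  x <- array(img, c(side[1], side[2], 1L, 1L))
  r <- .encoder_fwd(enc$params, enc$plan, enc$config, enc$bn_state, x,
                    train = FALSE, keep_cache = FALSE)
  strides <- c(2L, 4L, 8L, 16L, 32L)
  pyr <- lapply(1:5, function(i) {
    v <- r$taps[[i]]
    d <- dim(v)
    dim(v) <- c(d[1], d[2], d[4])
    list(values = v, level = i, stride = strides[i], channels = d[4])
  })
  structure(pyr, class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("<feature_pyramid> 5 levels\n")
  for (f in x) {
    cat(sprintf("  level %d: stride %2d, %3d channels, %dx%d\n",
                f$level, f$stride, f$channels, dim(f$values)[1], dim(f$values)[2]))
  }
  invisible(x)
}
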