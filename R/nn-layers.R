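# Low-level neural-network layer math.
#
# All spatial tensors use the layout (H, W, N, C): rows top->bottom, columns
# left->right, batch, channels. Column-major flattening therefore gives
# matrices of shape (H*W*N, C) whose columns are channels, which maps every
# 1x1 convolution and batch-norm moment onto a single BLAS call.
#
# Parameters live in a flat named list; gradients are accumulated into an
# environment under the same names by the backward functions.

.grad_env <- function() new.env(parent = emptyenv())

.acc_grad <- function(gr, name, g) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

.as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

.as_hwnc <- function(x, H, W, N, C) {
  dim(x) <- c(H, W, N, C)
  x
}

# zero-pad one pixel on every spatial side ("same" padding for 3x3 kernels;
# stride-2 layers then produce ceil(side / 2))
.pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

# padded-row indices of kernel tap (i, j) for an output of Ho rows at the
# given stride: tap i reads padded rows stride*r_o - stride + i
.tap_idx <- function(n_out, stride, i) stride * seq_len(n_out) - stride + i

## ---- activations ----

.swish_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, sig = s)
}

.swish_bwd <- function(dout, cache, x) {
  s <- cache$sig
  dout * (s * (1 + x * (1 - s)))
}

.relu_fwd <- function(x) {
  x * (x > 0)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 1x1 convolution (pointwise): a matmul over channels ----

.conv1x1_init <- function(cin, cout, bias = FALSE, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cout)   # fan-out scaled normal
  p <- list(W = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout))
  if (bias) p$b <- numeric(cout)
  p
}

.conv1x1_fwd <- function(x, P, prefix) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  out <- .as_mat(x) %*% W
  b <- P[[paste0(prefix, ".b")]]
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  .as_hwnc(out, d[1], d[2], d[3], ncol(W))
}

.conv1x1_bwd <- function(dout, x, P, prefix, gr) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  dm <- .as_mat(dout)
  xm <- .as_mat(x)
  .acc_grad(gr, paste0(prefix, ".W"), crossprod(xm, dm))
  if (!is.null(P[[paste0(prefix, ".b")]])) {
    .acc_grad(gr, paste0(prefix, ".b"), colSums(dm))
  }
  .as_hwnc(dm %*% t(W), d[1], d[2], d[3], d[4])
}

## ---- full 3x3 convolution (stem): nine shifted matmuls ----

.conv3x3_init <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cout))
  list(W = array(stats::rnorm(9 * cin * cout, sd = sd), c(3, 3, cin, cout)))
}

.conv3x3_fwd <- function(x, P, prefix, stride = 1L) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  cout <- dim(W)[4]
  Ho <- as.integer(ceiling(d[1] / stride)); Wo <- as.integer(ceiling(d[2] / stride))
  xp <- .pad1(x)
  acc <- matrix(0, Ho * Wo * d[3], cout)
  for (i in 1:3) for (j in 1:3) {
    xs <- xp[.tap_idx(Ho, stride, i), .tap_idx(Wo, stride, j), , , drop = FALSE]
    dim(xs) <- c(Ho * Wo * d[3], d[4])
    acc <- acc + xs %*% matrix(W[i, j, , ], d[4], cout)
  }
  .as_hwnc(acc, Ho, Wo, d[3], cout)
}

.conv3x3_bwd <- function(dout, x, P, prefix, stride, gr) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  cin <- d[4]; cout <- dim(W)[4]
  do_ <- dim(dout); Ho <- do_[1]; Wo <- do_[2]
  xp <- .pad1(x)
  dm <- .as_mat(dout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (i in 1:3) for (j in 1:3) {
    ri <- .tap_idx(Ho, stride, i); ci <- .tap_idx(Wo, stride, j)
    xs <- xp[ri, ci, , , drop = FALSE]
    dim(xs) <- c(Ho * Wo * d[3], cin)
    dW[i, j, , ] <- crossprod(xs, dm)
    dpart <- dm %*% t(matrix(W[i, j, , ], cin, cout))
    dim(dpart) <- c(Ho, Wo, d[3], cin)
    dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dpart
  }
  .acc_grad(gr, paste0(prefix, ".W"), dW)
  dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE]
}

## ---- 3x3 depthwise convolution ----

.dwconv3x3_init <- function(c) {
  sd <- sqrt(2 / 9)
  list(W = array(stats::rnorm(9 * c, sd = sd), c(3, 3, c)))
}

.dwconv3x3_fwd <- function(x, P, prefix, stride = 1L) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  Ho <- as.integer(ceiling(d[1] / stride)); Wo <- as.integer(ceiling(d[2] / stride))
  hw <- Ho * Wo * d[3]
  xp <- .pad1(x)
  acc <- array(0, c(Ho, Wo, d[3], d[4]))
  for (i in 1:3) for (j in 1:3) {
    xs <- xp[.tap_idx(Ho, stride, i), .tap_idx(Wo, stride, j), , , drop = FALSE]
    acc <- acc + xs * rep(W[i, j, ], each = hw)
  }
  acc
}

.dwconv3x3_bwd <- function(dout, x, P, prefix, stride, gr) {
  d <- dim(x)
  W <- P[[paste0(prefix, ".W")]]
  do_ <- dim(dout); Ho <- do_[1]; Wo <- do_[2]
  hw <- Ho * Wo * d[3]
  xp <- .pad1(x)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (i in 1:3) for (j in 1:3) {
    ri <- .tap_idx(Ho, stride, i); ci <- .tap_idx(Wo, stride, j)
    xs <- xp[ri, ci, , , drop = FALSE]
    dW[i, j, ] <- colSums(.as_mat(xs * dout))
    dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dout * rep(W[i, j, ], each = hw)
  }
  .acc_grad(gr, paste0(prefix, ".W"), dW)
  dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE]
}

## ---- batch normalization (per channel over H, W, N) ----

.bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

.bn_state_init <- function(c) {
  list(mean = numeric(c), var = rep(1, c))
}

.bn_fwd <- function(x, P, prefix, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- .as_mat(x)
  gamma <- P[[paste0(prefix, ".gamma")]]
  beta <- P[[paste0(prefix, ".beta")]]
  n <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)        # biased variance, standard for BN
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(invstd, each = n)
    st <- state[[prefix]]
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * v
    state[[prefix]] <- st
    out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
    list(out = .as_hwnc(out, d[1], d[2], d[3], d[4]), state = state,
         cache = list(xhat = xhat, invstd = invstd, n = n, d = d))
  } else {
    st <- state[[prefix]]
    invstd <- 1 / sqrt(st$var + eps)
    out <- (xm - rep(st$mean, each = n)) * rep(invstd * gamma, each = n) + rep(beta, each = n)
    list(out = .as_hwnc(out, d[1], d[2], d[3], d[4]), state = state, cache = NULL)
  }
}

.bn_bwd <- function(dout, cache, P, prefix, gr) {
  gamma <- P[[paste0(prefix, ".gamma")]]
  n <- cache$n
  dm <- .as_mat(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  .acc_grad(gr, paste0(prefix, ".gamma"), dgamma)
  .acc_grad(gr, paste0(prefix, ".beta"), dbeta)
  coef <- rep(gamma * cache$invstd / n, each = n)
  dx <- coef * (n * dm - rep(dbeta, each = n) - xhat * rep(dgamma, each = n))
  d <- cache$d
  .as_hwnc(dx, d[1], d[2], d[3], d[4])
}

## ---- dense (fully connected) ----

.dense_init <- function(din, dout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / din)
  list(W = matrix(stats::rnorm(din * dout, sd = sd), din, dout), b = numeric(dout))
}

.dense_fwd <- function(x, P, prefix) {
  W <- P[[paste0(prefix, ".W")]]
  x %*% W + rep(P[[paste0(prefix, ".b")]], each = nrow(x))
}

.dense_bwd <- function(dout, x, P, prefix, gr) {
  .acc_grad(gr, paste0(prefix, ".W"), crossprod(x, dout))
  .acc_grad(gr, paste0(prefix, ".b"), colSums(dout))
  dout %*% t(P[[paste0(prefix, ".W")]])
}

## ---- global average pool over H, W (per sample and channel) ----

.gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  s <- colMeans(xm)
  matrix(s, d[3], d[4])
}

.gap_bwd <- function(ds, d) {
  # broadcast ds (N, C) back to (H, W, N, C) / (H*W)
  hw <- d[1] * d[2]
  g <- rep(as.vector(ds) / hw, each = hw)
  array(g, d)
}

## ---- Adam ----

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# prefix every name in a parameter list
.with_prefix <- function(p, prefix) {
  names(p) <- paste0(prefix, ".", names(p))
  p
}
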