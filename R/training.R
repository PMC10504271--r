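# Seeded training loop: softmax cross-entropy over query pixels, Adam with
# constant learning rate, best-by-validation-Dice checkpointing.

#' Training configuration
#'
#' Defaults follow the study protocol for the feature-alignment ablation:
#' cross-entropy loss, Adam, learning rate 0.001, batch size 16, 80 epochs.
#' Desk-scale runs typically lower `epochs` and `batch_size`.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Images per gradient step (>= 1).
#' @param learning_rate Adam learning rate (> 0), constant throughout.
#' @param seed Integer seed covering weight noise, data order and query
#'   sampling.
#' @param queries_per_step Number of query pixels sampled per image per step;
#'   `NULL` (default) uses the full output grid. Sampling coordinates is the
#'   usual way to train coordinate read-outs cheaply; uniform sampling keeps
#'   the loss an unbiased estimate of the full-grid loss.
#' @param positive_fraction When set (e.g. 0.5) and queries are sampled, this
#'   fraction of each image's sampled queries is drawn from its lesion pixels
#'   (with replacement when the lesion is smaller). This is class-balanced
#'   query sampling -- equivalent to a class-weighted cross-entropy -- and is
#'   the standard remedy when lesions occupy a small fraction of pixels;
#'   `NULL` (default) keeps plain uniform sampling.
#' @param track_train_dice Also evaluate Dice on the training set each epoch.
#' @param include_lesion_free_slices Kept with the dataset interface: when a
#'   manifest is used to assemble tensors, lesion-free slices are included by
#'   default, matching a clinical slice mix.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 16L, learning_rate = 0.001,
                         seed = 1L, queries_per_step = NULL,
                         positive_fraction = NULL,
                         track_train_dice = FALSE,
                         include_lesion_free_slices = TRUE) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!is.null(positive_fraction) &&
      (positive_fraction <= 0 || positive_fraction >= 1)) {
    stop("positive_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 queries_per_step = queries_per_step,
                 positive_fraction = positive_fraction,
                 track_train_dice = isTRUE(track_train_dice),
                 include_lesion_free_slices = isTRUE(include_lesion_free_slices)),
            class = "train_config")
}

#' Pixel-wise softmax cross-entropy
#'
#' Mean over pixels of the negative log-probability of the true class under
#' the softmax of the logits.
#'
#' @param logits `H x W x num_classes` array or `n x num_classes` matrix.
#' @param gt_mask Matching `H x W` 0/1 matrix or length-`n` label vector.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(logits, gt_mask) {
  d <- dim(logits)
  if (length(d) == 3L) {
    if (!all(d[1:2] == dim(gt_mask))) stop("logits and gt_mask shapes differ", call. = FALSE)
    dim(logits) <- c(d[1] * d[2], d[3])
    gt_mask <- as.vector(gt_mask)
  } else if (nrow(logits) != length(gt_mask)) {
    stop("logits and gt_mask shapes differ", call. = FALSE)
  }
  .ce_loss(logits, as.integer(gt_mask))$loss
}

# loss + gradient; labels are 0-based class indices
.ce_loss <- function(logits, labels) {
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  loss <- mean(log(Z) + mx - picked)
  grad <- p
  grad[cbind(seq_len(n), labels + 1L)] <- grad[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, grad = grad / n)
}

# pooled Dice of model predictions over a stack of images
.eval_dice <- function(model, images, masks) {
  N <- dim(images)[3]
  tp <- fp <- fn <- 0
  for (i in seq_len(N)) {
    pred <- stats::predict(model, images[, , i])
    gt <- masks[, , i]
    tp <- tp + sum(pred == 1 & gt == 1)
    fp <- fp + sum(pred == 1 & gt == 0)
    fn <- fn + sum(pred == 0 & gt == 1)
  }
  if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Train a feature-alignment segmentation model
#'
#' Stochastic gradient training with Adam on softmax cross-entropy over
#' query pixels. Every source of randomness (data order, query sampling)
#' flows from `config$seed`, so runs are bit-reproducible on CPU. When
#' validation data is supplied, the parameters with the best validation Dice
#' are retained as the fitted model.
#'
#' @param model An [efanet_model()].
#' @param data `list(images =, masks =)` with `(side, side, N)` arrays;
#'   images normalized to `[0, 1]`, masks 0/1, side divisible by 32.
#' @param config A [train_config()].
#' @param val_data Optional validation list with the same structure.
#' @return Object of class `efanet_fit`: the fitted `model`, a `history`
#'   tibble (epoch, loss, train_dice, val_dice), `best_epoch` and the config.
#' @export
train_efanet <- function(model, data, config = train_config(), val_data = NULL) {
  stopifnot(inherits(model, "efanet_model"))
  images <- data$images; masks <- data$masks
  if (is.null(images) || length(dim(images)) != 3L) stop("data$images must be (side, side, N)", call. = FALSE)
  N <- dim(images)[3]
  if (N < 1L) stop("empty training set", call. = FALSE)
  H <- dim(images)[1]; W <- dim(images)[2]
  set.seed(config$seed)

  full_queries <- cbind(rep(pixel_centers(H), times = W), rep(pixel_centers(W), each = H))
  nq_full <- nrow(full_queries)
  nq_step <- if (is.null(config$queries_per_step)) nq_full else min(config$queries_per_step, nq_full)
  masks_flat <- masks
  dim(masks_flat) <- c(H * W, N)

  P <- model$params
  opt <- .adam_init(P)
  history <- vector("list", config$epochs)
  best_dice <- -Inf
  best <- list(params = P, state = model$bn_state, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(N)
    losses <- c()
    for (lo in seq(1L, N, by = config$batch_size)) {
      bi <- order_idx[lo:min(lo + config$batch_size - 1L, N)]
      x <- array(images[, , bi], c(H, W, length(bi), 1L))
      if (nq_step < nq_full && !is.null(config$positive_fraction)) {
        # class-balanced per-image query sets
        n_pos_target <- round(config$positive_fraction * nq_step)
        queries <- vector("list", length(bi))
        labels <- integer(0)
        for (jj in seq_along(bi)) {
          pos <- which(masks_flat[, bi[jj]] == 1L)
          qp <- if (length(pos) > 0L) {
            pos[sample.int(length(pos), n_pos_target, replace = TRUE)]
          } else integer(0)
          qu <- sample.int(nq_full, nq_step - length(qp))
          qi <- c(qp, qu)
          queries[[jj]] <- full_queries[qi, , drop = FALSE]
          labels <- c(labels, as.integer(masks_flat[qi, bi[jj]]))
        }
      } else {
        qi <- if (nq_step < nq_full) sort(sample.int(nq_full, nq_step)) else seq_len(nq_full)
        queries <- full_queries[qi, , drop = FALSE]
        labels <- as.integer(masks_flat[qi, bi])
      }

      model$params <- P
      fwd <- .model_fwd(model, x, queries, train = TRUE)
      model$bn_state <- fwd$lf$state
      ce <- .ce_loss(fwd$logits, labels)
      losses <- c(losses, ce$loss)
      gr <- .grad_env()
      .model_bwd(model, fwd, ce$grad, gr)
      upd <- .adam_step(P, as.list(gr), opt, config$learning_rate)
      P <- upd$params
      opt <- upd$opt
    }
    model$params <- P
    train_dice <- if (config$track_train_dice) .eval_dice(model, images, masks) else NA_real_
    val_dice <- if (!is.null(val_data)) .eval_dice(model, val_data$images, val_data$masks) else NA_real_
    history[[epoch]] <- c(epoch = epoch, loss = mean(losses),
                          train_dice = train_dice, val_dice = val_dice)
    score <- if (!is.null(val_data)) val_dice else -mean(losses)
    if (score > best_dice) {
      best_dice <- score
      best <- list(params = P, state = model$bn_state, epoch = epoch)
    }
  }

  hist_df <- tibble::as_tibble(do.call(rbind, history))
  fitted <- model
  fitted$params <- best$params
  fitted$bn_state <- best$state
  structure(list(model = fitted, history = hist_df, best_epoch = best$epoch,
                 config = config), class = "efanet_fit")
}

#' @export
print.efanet_fit <- function(x, ...) {
  cat("<efanet_fit> epochs:", nrow(x$history), "\n")
  last <- x$history[nrow(x$history), ]
  cat("  final loss:", signif(last$loss, 4))
  if (!is.na(last$val_dice)) cat("  best val Dice:", signif(max(x$history$val_dice), 4),
                                 "(epoch", x$best_epoch, ")")
  cat("\n")
  invisible(x)
}

#' Tidy a fitted model's training history
#'
#' @param x An `efanet_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `train_dice`,
#'   `val_dice`.
#' @method tidy efanet_fit
#' @export
tidy.efanet_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `efanet_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_loss`, `best_epoch`, `best_val_dice`,
#'   `parameters`.
#' @method glance efanet_fit
#' @export
glance.efanet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    best_epoch = x$best_epoch,
    best_val_dice = if (all(is.na(x$history$val_dice))) NA_real_ else max(x$history$val_dice, na.rm = TRUE),
    parameters = count_parameters(x$model))
}

#' Plot a training history
#'
#' @param object An `efanet_fit`.
#' @param ... Unused.
#' @return A ggplot of loss (and Dice curves when tracked) against epoch.
#' @method autoplot efanet_fit
#' @export
autoplot.efanet_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, metric = "loss", value = h$loss),
    if (!all(is.na(h$train_dice))) data.frame(epoch = h$epoch, metric = "train Dice", value = h$train_dice),
    if (!all(is.na(h$val_dice))) data.frame(epoch = h$epoch, metric = "val Dice", value = h$val_dice))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}
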