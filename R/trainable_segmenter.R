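## Lightweight trainable nucleus segmenter.
##
## A multiscale filter bank (identity, Gaussians at several scales,
## difference-of-Gaussians, Laplacian and Sobel magnitudes) encodes each pixel
## into a feature vector, and a logistic decoder maps features to a
## foreground probability. The decoder is trained by full-batch gradient
## descent on a binary cross-entropy + dice-loss objective, with a held-out
## validation split and per-epoch IOU tracking. It drops into the
## segmentation path via `seg_config(method = "cnn", model = ...)`; the
## classical path remains the default.

#' Training configuration for the trainable segmenter
#'
#' @param val_fraction fraction of pairs held out for validation (in (0, 1);
#'   a validation split is mandatory).
#' @param epochs gradient-descent epochs.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param dice_weight weight of the soft dice loss added to mean binary
#'   cross-entropy.
#' @param pixels_per_image training pixels sampled per image (balanced
#'   between foreground and background where possible).
#' @param seed seed controlling the split and pixel sampling; with a fixed
#'   seed training is fully deterministic.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(val_fraction = 0.25, epochs = 80L, lr = 0.5,
                         momentum = 0.9, dice_weight = 0.5,
                         pixels_per_image = 1500L, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1): a validation split is required")
  structure(list(val_fraction = val_fraction, epochs = as.integer(epochs),
                 lr = lr, momentum = momentum, dice_weight = dice_weight,
                 pixels_per_image = as.integer(pixels_per_image),
                 seed = as.integer(seed)),
            class = "train_config")
}

## Filter-bank features for one image: columns are per-pixel descriptors.
segmenter_features <- function(image) {
  img <- EBImage::Image(image)
  g1 <- EBImage::imageData(EBImage::gblur(img, 1))
  g2 <- EBImage::imageData(EBImage::gblur(img, 2))
  g4 <- EBImage::imageData(EBImage::gblur(img, 4))
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  sob_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  lap <- abs(EBImage::imageData(EBImage::filter2(img, lap_k)))
  gx <- EBImage::imageData(EBImage::filter2(img, sob_x))
  gy <- EBImage::imageData(EBImage::filter2(img, t(sob_x)))
  cbind(as.vector(image), as.vector(g1), as.vector(g2), as.vector(g4),
        as.vector(image - g2), as.vector(lap), as.vector(sqrt(gx^2 + gy^2)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

iou_binary <- function(pred, truth) {
  u <- sum(pred | truth)
  if (u == 0) 1 else sum(pred & truth) / u
}

#' Train the pixel-wise nucleus segmenter
#'
#' Splits the pairs into training and validation sets, samples a balanced set
#' of pixels per training image, standardises the filter-bank features, and
#' optimises a logistic decoder by full-batch gradient descent with momentum
#' on mean binary cross-entropy plus \code{dice_weight} x soft dice loss.
#' Per-epoch training/validation IOU (at probability 0.5) is recorded, and
#' the final model carries the mean per-image validation IOU computed on the
#' full held-out images.
#'
#' @param pairs list of \code{list(image, mask)} pairs (>= 2), e.g. from
#'   \code{\link{generate_training_pairs}}.
#' @param config a \code{\link{train_config}}.
#' @return Object of class \code{segmenter_model}: list with \code{weights},
#'   \code{feature_mean}, \code{feature_sd}, \code{history} (per-epoch
#'   data.frame \code{epoch, loss, train_iou, val_iou}),
#'   \code{val_iou} (final full-image validation IOU),
#'   \code{baseline_val_iou} (all-background prediction on the same split),
#'   and \code{val_idx}.
#' @export
train_segmenter <- function(pairs, config = train_config()) {
  if (length(pairs) < 2L) stop("need at least 2 training pairs")
  set.seed(config$seed)
  n <- length(pairs)
  n_val <- max(1L, round(config$val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training pairs")
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)

  sample_pixels <- function(idx) {
    Xs <- list(); ys <- list()
    for (i in idx) {
      feats <- segmenter_features(pairs[[i]]$image)
      lab <- as.vector(pairs[[i]]$mask) > 0
      fg <- which(lab); bg <- which(!lab)
      k <- config$pixels_per_image
      take_fg <- sample(fg, min(length(fg), k %/% 2))
      take_bg <- sample(bg, min(length(bg), k - length(take_fg)))
      take <- c(take_fg, take_bg)
      Xs[[length(Xs) + 1L]] <- feats[take, , drop = FALSE]
      ys[[length(ys) + 1L]] <- lab[take]
    }
    list(X = do.call(rbind, Xs), y = as.numeric(unlist(ys)))
  }
  tr <- sample_pixels(train_idx)
  va <- sample_pixels(val_idx)

  mu <- colMeans(tr$X)
  sdv <- apply(tr$X, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xt <- cbind(1, std(tr$X)); yt <- tr$y
  Xv <- cbind(1, std(va$X)); yv <- va$y

  w <- rep(0, ncol(Xt))
  vel <- rep(0, ncol(Xt))
  N <- nrow(Xt)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_iou = numeric(0), val_iou = numeric(0))
  for (ep in seq_len(config$epochs)) {
    p <- sigmoid(drop(Xt %*% w))
    eps <- 1e-12
    bce <- -mean(yt * log(p + eps) + (1 - yt) * log(1 - p + eps))
    A <- sum(p * yt); B <- sum(p) + sum(yt)
    dice_loss <- 1 - 2 * A / max(B, eps)
    loss <- bce + config$dice_weight * dice_loss
    if (!is.finite(loss))
      stop("non-finite loss at epoch ", ep,
           " (lr too high or degenerate features); loss = ", loss)
    g_bce <- crossprod(Xt, p - yt) / N
    dl_dp <- -2 * (yt * B - A) / max(B, eps)^2
    g_dice <- crossprod(Xt, dl_dp * p * (1 - p))
    g <- drop(g_bce + config$dice_weight * g_dice)
    vel <- config$momentum * vel - config$lr * g
    w <- w + vel
    hist <- rbind(hist, data.frame(
      epoch = ep, loss = loss,
      train_iou = iou_binary(p > 0.5, yt > 0.5),
      val_iou = iou_binary(sigmoid(drop(Xv %*% w)) > 0.5, yv > 0.5)))
  }

  model <- structure(list(weights = w, feature_mean = mu, feature_sd = sdv,
                          history = hist, config = config,
                          val_idx = val_idx),
                     class = "segmenter_model")
  per_img <- vapply(val_idx, function(i) {
    pm <- predict_segmenter(model, pairs[[i]]$image)
    iou_binary(pm > 0.5, pairs[[i]]$mask > 0)
  }, 0)
  base <- vapply(val_idx, function(i)
    iou_binary(matrix(FALSE, nrow(pairs[[i]]$mask), ncol(pairs[[i]]$mask)),
               pairs[[i]]$mask > 0), 0)
  model$val_iou <- mean(per_img)
  model$baseline_val_iou <- mean(base)
  model
}

#' Predict a foreground-probability map
#'
#' @param model a \code{segmenter_model} from \code{\link{train_segmenter}}.
#' @param image single-channel matrix in [0, 1].
#' @return Matrix of per-pixel foreground probabilities, same shape as
#'   \code{image}.
#' @export
predict_segmenter <- function(model, image) {
  stopifnot(inherits(model, "segmenter_model"))
  X <- segmenter_features(image)
  X <- sweep(sweep(X, 2, model$feature_mean), 2, model$feature_sd, "/")
  p <- sigmoid(drop(cbind(1, X) %*% model$weights))
  matrix(p, nrow(image), ncol(image))
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf(
    "segmenter_model: %d features, %d epochs, validation IOU %.3f (baseline %.3f)\n",
    length(x$weights) - 1L, nrow(x$history), x$val_iou, x$baseline_val_iou))
  invisible(x)
}
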