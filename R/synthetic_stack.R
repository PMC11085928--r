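## Synthetic nuclei z-stacks with exact ground truth.
##
## Images are matrices indexed [x, y] (EBImage orientation); layer indices are
## 0-based with layer 0 the first acquired (seeding-surface) plane. Nuclei are
## rendered as filled ellipses that reappear in neighbouring layers blurred by
## a Gaussian whose scale grows linearly with defocus distance and attenuated
## as 1/(1 + sigma^2), so "in focus" is well defined and recoverable.

#' Parameters of a synthetic nuclei z-stack
#'
#' Bundles the geometry, optics and randomness of a synthetic stack. Defaults
#' describe the reference study condition used throughout the package's
#' validation: 14 layers at a 7 micron z-step, a 1024 px square field at
#' 0.5 micron/px, 200 fibroblast-sized nuclei whose depth follows a Hill
#' colonisation profile, defocus blur growing by 1 px sigma per layer of
#' distance, and 2% additive Gaussian noise.
#'
#' @param n_layers number of z-layers (>= 2).
#' @param layer_spacing_um physical z-step between layers, microns.
#' @param width_px,height_px frame size in pixels.
#' @param pixel_size_um lateral pixel size, microns.
#' @param n_nuclei number of nuclei to place (0 allowed: pure-noise stack).
#' @param major_um_range,minor_um_range ranges of the full major/minor nuclear
#'   axis lengths, microns.
#' @param depth_distribution list describing where nuclei sit in depth: one of
#'   \code{list(model = "surface", k = ...)} (exponential settling from the
#'   seeding surface, rate \code{k} per micron),
#'   \code{list(model = "exponential", k = ..., z0 = ...)} (mass shifted below
#'   depth \code{z0}), or \code{list(model = "hill", n = ..., K = ...)}
#'   (sigmoidal colonisation, half-depth \code{K} microns, exponent \code{n}).
#' @param blur_growth Gaussian-blur sigma increment (px) per layer of defocus.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensities live in [0, 1]).
#' @param min_separation_px minimum centre-to-centre distance between nuclei;
#'   default 1.1 x the largest major axis in px, so nuclei never overlap
#'   laterally and ground-truth matching is unambiguous.
#' @param seed integer seed fixing all randomness.
#' @return An object of class \code{stack_params}.
#' @export
stack_params <- function(n_layers = 14L,
                         layer_spacing_um = 7,
                         width_px = 1024L,
                         height_px = 1024L,
                         pixel_size_um = 0.5,
                         n_nuclei = 200L,
                         major_um_range = c(12, 18),
                         minor_um_range = c(7, 11),
                         depth_distribution = list(model = "hill", n = 3, K = 40),
                         blur_growth = 1.0,
                         noise_sd = 0.02,
                         min_separation_px = NULL,
                         seed = 1L) {
  p <- list(n_layers = as.integer(n_layers),
            layer_spacing_um = layer_spacing_um,
            width_px = as.integer(width_px), height_px = as.integer(height_px),
            pixel_size_um = pixel_size_um,
            n_nuclei = as.integer(n_nuclei),
            major_um_range = sort(major_um_range),
            minor_um_range = sort(minor_um_range),
            depth_distribution = depth_distribution,
            blur_growth = blur_growth,
            noise_sd = noise_sd,
            min_separation_px = min_separation_px,
            seed = as.integer(seed))
  if (is.null(p$min_separation_px))
    p$min_separation_px <- 1.1 * max(p$major_um_range) / p$pixel_size_um
  class(p) <- "stack_params"
  validate_stack_params(p)
  p
}

validate_stack_params <- function(p) {
  stopifnot(inherits(p, "stack_params"))
  if (p$n_layers < 2L) stop("n_layers must be >= 2")
  if (p$layer_spacing_um <= 0 || p$pixel_size_um <= 0)
    stop("layer spacing and pixel size must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (any(p$major_um_range <= 0) || any(p$minor_um_range <= 0))
    stop("axis ranges must be positive")
  if (max(p$minor_um_range) > max(p$major_um_range))
    stop("minor axis range must not exceed major axis range")
  max_major_px <- max(p$major_um_range) / p$pixel_size_um
  if (max_major_px + 4 >= min(p$width_px, p$height_px))
    stop("nucleus larger than frame: reduce axis range or enlarge frame")
  depth_cdf(p$depth_distribution, 0)  # validates the model spec
  invisible(p)
}

#' Cumulative depth distribution of the colonisation models
#'
#' Evaluates the cumulative fraction of cell mass at or above depth \code{z}
#' for the three depth models: \code{surface} (exponential settling,
#' \eqn{F(z) = 1 - e^{-kz}}), \code{exponential} (the same law shifted to start
#' at depth \code{z0}), and \code{hill} (\eqn{F(z) = z^n / (K^n + z^n)}).
#'
#' @param model list with a \code{model} name and its parameters
#'   (see \code{\link{stack_params}}).
#' @param z depth(s) in microns, >= 0.
#' @return Numeric vector of cumulative fractions in [0, 1].
#' @export
depth_cdf <- function(model, z) {
  if (!is.list(model) || is.null(model$model))
    stop("depth model must be a list with a 'model' name")
  switch(model$model,
    surface = {
      if (is.null(model$k) || model$k <= 0) stop("surface model needs k > 0")
      1 - exp(-model$k * z)
    },
    exponential = {
      if (is.null(model$k) || model$k <= 0) stop("exponential model needs k > 0")
      z0 <- if (is.null(model$z0)) 0 else model$z0
      pmax(0, 1 - exp(-model$k * (z - z0)))
    },
    hill = {
      if (is.null(model$n) || is.null(model$K) || model$n <= 0 || model$K <= 0)
        stop("hill model needs n > 0 and K > 0")
      ifelse(z <= 0, 0, z^model$n / (model$K^model$n + z^model$n))
    },
    stop("unknown depth model: ", model$model)
  )
}

## Per-layer occupancy probabilities. Layer k spans depth [k, k+1) x spacing;
## the deepest layer absorbs the tail mass so probabilities sum to 1 and the
## cumulative fraction through layer k equals F((k+1) x spacing) exactly for
## all but the last layer.
layer_probabilities <- function(model, n_layers, spacing_um) {
  zb <- (0:n_layers) * spacing_um
  F <- depth_cdf(model, zb)
  p <- diff(F)
  p[n_layers] <- 1 - F[n_layers]
  if (any(p < -1e-12)) stop("depth model produced a decreasing CDF")
  pmax(p, 0)
}

## Dart-throwing placement with a minimum separation; margin keeps whole
## ellipses inside the frame.
place_centroids <- function(n, width, height, margin, min_sep) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (2 * margin >= width || 2 * margin >= height)
    stop("frame too small for the requested nucleus size")
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " nuclei with min separation ", min_sep,
           " px in a ", width, "x", height, " frame")
    cx <- runif(1, 1 + margin, width - margin)
    cy <- runif(1, 1 + margin, height - margin)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    xs[placed] <- cx; ys[placed] <- cy
  }
  cbind(x = xs, y = ys)
}

## Adds a filled ellipse (semi-axes a, b px, orientation theta) to a canvas by
## max-combination, touching only its bounding box.
render_ellipse <- function(canvas, cx, cy, a, b, theta, value) {
  r <- a + 1
  x0 <- max(1L, floor(cx - r)); x1 <- min(nrow(canvas), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(ncol(canvas), ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  patch <- canvas[xs, ys, drop = FALSE]
  canvas[xs, ys] <- pmax(patch, value * inside)
  canvas
}

#' Generate a synthetic nuclei z-stack with exact ground truth
#'
#' Places \code{n_nuclei} elliptical nuclei at depths drawn from the configured
#' colonisation model and renders every layer of the stack: a nucleus appears
#' sharp in its true layer and, in other layers, convolved with an isotropic
#' Gaussian of sigma \code{blur_growth x |layer - true_layer|} px and
#' attenuated by \eqn{1/(1+\sigma^2)}; appearances attenuated below 1% are
#' omitted. Additive Gaussian noise is applied last. All randomness flows from
#' \code{params$seed}, so identical parameters give bit-identical stacks.
#'
#' @param params a \code{\link{stack_params}} object.
#' @return A list with \code{stack} (class \code{nuc_stack}: list of layer
#'   matrices plus calibration) and \code{truth} (class \code{ground_truth}:
#'   a data.frame \code{id, layer, x_px, y_px, major_um, minor_um,
#'   orientation_rad} with per-layer true counts in
#'   \code{attr(truth, "per_layer_counts")}).
#' @export
generate_stack <- function(params) {
  validate_stack_params(params)
  set.seed(params$seed)
  n <- params$n_nuclei
  nl <- params$n_layers
  W <- params$width_px; H <- params$height_px
  ps <- params$pixel_size_um

  probs <- layer_probabilities(params$depth_distribution, nl,
                               params$layer_spacing_um)
  true_layer <- if (n > 0) sample.int(nl, n, replace = TRUE, prob = probs) - 1L
                else integer(0)
  major_um <- runif(n, params$major_um_range[1], params$major_um_range[2])
  minor_um <- runif(n, params$minor_um_range[1], params$minor_um_range[2])
  swap <- minor_um > major_um
  if (any(swap)) { tmp <- major_um[swap]; major_um[swap] <- minor_um[swap]; minor_um[swap] <- tmp }
  orientation <- runif(n, 0, pi)
  intensity <- runif(n, 0.75, 0.95)
  margin <- max(params$major_um_range) / ps / 2 + 2
  cen <- place_centroids(n, W, H, margin, params$min_separation_px)

  truth <- data.frame(id = seq_len(n), layer = true_layer,
                      x_px = cen[, "x"], y_px = cen[, "y"],
                      major_um = major_um, minor_um = minor_um,
                      orientation_rad = orientation)
  attr(truth, "per_layer_counts") <- tabulate(true_layer + 1L, nbins = nl)
  class(truth) <- c("ground_truth", "data.frame")

  a_px <- major_um / ps / 2  # semi-axes in px
  b_px <- minor_um / ps / 2

  # A nucleus's appearance at defocus distance d is identical above and below
  # its true layer, so each (nucleus, d) patch is rendered and blurred once
  # (in a small window) and cached for reuse.
  patch_cache <- rep(list(list()), max(n, 1L))
  appearance <- function(i, d) {
    key <- as.character(d)
    pc <- patch_cache[[i]][[key]]
    if (!is.null(pc)) return(pc)
    sigma <- params$blur_growth * d
    r <- ceiling(a_px[i] + 3 * sigma) + 2L
    x0 <- round(cen[i, "x"]) - r
    y0 <- round(cen[i, "y"]) - r
    np <- 2L * r + 1L
    patch <- matrix(0, np, np)
    patch <- render_ellipse(patch, cen[i, "x"] - x0, cen[i, "y"] - y0,
                            a_px[i], b_px[i], orientation[i], intensity[i])
    if (sigma > 0)
      patch <- EBImage::imageData(EBImage::gblur(EBImage::Image(patch),
                                                 sigma = sigma))
    pc <- list(patch = patch, x0 = x0, y0 = y0, np = np)
    patch_cache[[i]][[key]] <<- pc
    pc
  }

  max_d_visible <- if (params$blur_growth > 0)
    floor(sqrt(1 / 0.01 - 1) / params$blur_growth) else Inf

  layers <- vector("list", nl)
  for (l in 0:(nl - 1L)) {
    img <- matrix(0, W, H)
    if (n > 0) {
      for (i in which(abs(true_layer - l) <= max_d_visible)) {
        d <- abs(true_layer[i] - l)
        atten <- 1 / (1 + (params$blur_growth * d)^2)
        pc <- appearance(i, d)
        xs <- max(1L, pc$x0 + 1L):min(W, pc$x0 + pc$np)
        ys <- max(1L, pc$y0 + 1L):min(H, pc$y0 + pc$np)
        img[xs, ys] <- img[xs, ys] +
          atten * pc$patch[xs - pc$x0, ys - pc$y0, drop = FALSE]
      }
    }
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(W * H, 0, params$noise_sd), W, H)
    layers[[l + 1L]] <- pmin(pmax(img, 0), 1)
  }

  stack <- new_nuc_stack(layers, params$layer_spacing_um, ps)
  list(stack = stack, truth = truth)
}

new_nuc_stack <- function(layers, layer_spacing_um, pixel_size_um) {
  structure(list(layers = layers,
                 layer_spacing_um = layer_spacing_um,
                 pixel_size_um = pixel_size_um),
            class = "nuc_stack")
}

#' @export
print.nuc_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("nuc_stack: %d layers of %d x %d px, z-step %g um, pixel %g um\n",
              length(x$layers), d[1], d[2], x$layer_spacing_um,
              x$pixel_size_um))
  invisible(x)
}

#' Generate image/mask training pairs of in-focus nuclei
#'
#' Renders stacks' worth of in-focus nuclei together with their exact binary
#' masks, for training and validating a segmenter. Optional augmentation
#' applies a random horizontal/vertical flip and quarter-turn rotation
#' identically to image and mask, plus a multiplicative intensity jitter to the
#' image alone.
#'
#' @param params a \code{\link{stack_params}} object; \code{width_px},
#'   \code{height_px}, \code{n_nuclei}, axis ranges, \code{noise_sd} and
#'   \code{seed} are used.
#' @param n_pairs number of pairs to generate (>= 1).
#' @param augment logical; apply augmentation.
#' @return List of \code{n_pairs} lists with elements \code{image} (matrix in
#'   [0, 1]) and \code{mask} (0/1 integer matrix).
#' @export
generate_training_pairs <- function(params, n_pairs, augment = FALSE) {
  validate_stack_params(params)
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  set.seed(params$seed)
  W <- params$width_px; H <- params$height_px
  ps <- params$pixel_size_um
  margin <- max(params$major_um_range) / ps / 2 + 2
  out <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    n <- params$n_nuclei
    cen <- place_centroids(n, W, H, margin, params$min_separation_px)
    major <- runif(n, params$major_um_range[1], params$major_um_range[2]) / ps / 2
    minor <- runif(n, params$minor_um_range[1], params$minor_um_range[2]) / ps / 2
    swap <- minor > major
    if (any(swap)) { tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp }
    th <- runif(n, 0, pi)
    val <- runif(n, 0.75, 0.95)
    img <- matrix(0, W, H); msk <- matrix(0, W, H)
    for (i in seq_len(n)) {
      img <- render_ellipse(img, cen[i, 1], cen[i, 2], major[i], minor[i], th[i], val[i])
      msk <- render_ellipse(msk, cen[i, 1], cen[i, 2], major[i], minor[i], th[i], 1)
    }
    if (params$noise_sd > 0)
      img <- pmin(pmax(img + matrix(rnorm(W * H, 0, params$noise_sd), W, H), 0), 1)
    if (augment) {
      if (runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
                            msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE] }
      if (runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
                            msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE] }
      k <- sample(0:3, 1)
      if (k > 0 && nrow(img) == ncol(img)) for (r in seq_len(k)) {
        img <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
        msk <- t(msk)[rev(seq_len(ncol(msk))), , drop = FALSE]
      }
      img <- pmin(pmax(img * runif(1, 0.85, 1.15), 0), 1)
    }
    storage.mode(msk) <- "integer"
    out[[j]] <- list(image = img, mask = msk)
  }
  out
}

#' Generate a per-layer count scenario from a depth model
#'
#' Draws a per-layer count profile whose cumulative fraction follows the named
#' colonisation model, optionally perturbed: Gaussian noise of sd
#' \code{noise_sd} is added to the cumulative fractions, which are then
#' re-monotonised and anchored at 1 in the deepest layer. Counts are
#' non-negative integers summing exactly to \code{total_cells}
#' (largest-remainder rounding).
#'
#' @param model model name: \code{"surface"}, \code{"exponential"} or
#'   \code{"hill"}.
#' @param model_params named list of the model's parameters (see
#'   \code{\link{depth_cdf}}).
#' @param n_layers number of layers.
#' @param total_cells total number of cells (>= 1).
#' @param noise_sd sd of the perturbation on cumulative fractions (0 = exact).
#' @param seed integer seed.
#' @param layer_spacing_um z-step in microns.
#' @param day optional day label carried on the profile.
#' @return A \code{\link{count_profile}}.
#' @export
generate_count_scenario <- function(model, model_params, n_layers, total_cells,
                                    noise_sd = 0, seed = 1L,
                                    layer_spacing_um = 7, day = NA) {
  if (total_cells < 1) stop("total_cells must be >= 1")
  spec <- c(list(model = model), model_params)
  zb <- (1:n_layers) * layer_spacing_um
  alpha <- depth_cdf(spec, zb)
  alpha[n_layers] <- 1
  if (noise_sd > 0) {
    set.seed(seed)
    alpha <- alpha + rnorm(n_layers, 0, noise_sd)
    alpha[n_layers] <- 1
    alpha <- pmin(pmax(cummax(alpha), 0), 1)
  }
  p <- diff(c(0, alpha))
  counts <- largest_remainder_round(p * total_cells, total_cells)
  count_profile(counts, layer_spacing_um = layer_spacing_um, day = day)
}

## Rounds non-negative reals to integers summing to `total`, assigning the
## leftover units to the largest fractional remainders (ties to lower index).
largest_remainder_round <- function(x, total) {
  x <- pmax(x, 0)
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - f)
    take <- ord[f[ord] > 0][seq_len(-rem)]
    f[take] <- f[take] - 1
  }
  as.integer(f)
}

#' Write a stack as a multi-page TIFF
#'
#' One 32-bit page per layer, top (first-acquired) layer as page 0. The
#' companion reader \code{\link{read_stack}} restores intensities to within
#' one quantisation unit (about 2e-10 on the [0, 1] scale).
#'
#' @param stack a \code{nuc_stack}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nuc_stack"))
  pages <- lapply(stack$layers, t)  # [x,y] -> row-major image
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write ground truth as CSV
#'
#' Header: \code{id,layer,x_px,y_px,major_um,minor_um,orientation_rad}.
#'
#' @param truth a \code{ground_truth} data.frame from
#'   \code{\link{generate_stack}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth)[, c("id", "layer", "x_px", "y_px",
                                            "major_um", "minor_um",
                                            "orientation_rad")],
                   path, row.names = FALSE)
  invisible(path)
}
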