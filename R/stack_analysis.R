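## From per-layer masks to one deduplicated nucleus table.
##
## A nucleus appears in several consecutive focal planes; detections are
## chained across layers when their centroids are close and their patches are
## structurally similar (SSIM), and each chain is assigned to its
## sharpest-focus member, so every physical nucleus is counted once.

#' Linking configuration for cross-layer deduplication
#'
#' @param max_centroid_shift_px maximum centroid distance (px) between
#'   detections of the same nucleus in different layers. The default, 36 px,
#'   is one nucleus major axis at the reference calibration (18 um at
#'   0.5 um/px).
#' @param ssim_threshold minimum SSIM between two patches for a link
#'   (in [-1, 1]).
#' @param ssim_window_px odd sliding-window width for SSIM.
#' @param focus_measure \code{"laplacian_variance"} (default) or
#'   \code{"tenengrad"}.
#' @param max_layer_gap number of missed intermediate layers a link may skip
#'   (0 = adjacent layers only; default 1).
#' @param patch_px patches are resized to this square window, and normalised
#'   to their own maximum, before SSIM: defocus attenuates brightness, and
#'   linking should compare structure rather than intensity.
#' @param patch_pad_px padding (px) around a detection's bounding box when
#'   cropping its patch.
#' @return An object of class \code{link_config}.
#' @export
link_config <- function(max_centroid_shift_px = 36,
                        ssim_threshold = 0.5,
                        ssim_window_px = 7L,
                        focus_measure = c("laplacian_variance", "tenengrad"),
                        max_layer_gap = 1L,
                        patch_px = 32L,
                        patch_pad_px = 4L) {
  focus_measure <- match.arg(focus_measure)
  if (max_centroid_shift_px <= 0) stop("max_centroid_shift_px must be > 0")
  if (ssim_window_px %% 2L != 1L) stop("ssim_window_px must be odd")
  if (abs(ssim_threshold) > 1) stop("ssim_threshold must be in [-1, 1]")
  structure(list(max_centroid_shift_px = max_centroid_shift_px,
                 ssim_threshold = ssim_threshold,
                 ssim_window_px = as.integer(ssim_window_px),
                 focus_measure = focus_measure,
                 max_layer_gap = as.integer(max_layer_gap),
                 patch_px = as.integer(patch_px),
                 patch_pad_px = as.integer(patch_pad_px)),
            class = "link_config")
}

#' Sharpness of an image patch
#'
#' \code{laplacian_variance} is the variance of the 4-neighbour Laplacian over
#' the patch interior; \code{tenengrad} is the mean squared Sobel gradient
#' magnitude. Both are non-negative, zero on a constant patch, and larger for
#' sharper patches; defocus blur lowers them monotonically.
#'
#' @param patch numeric matrix, at least 3 x 3.
#' @param measure focus measure name.
#' @return Non-negative scalar.
#' @export
focus_score <- function(patch, measure = c("laplacian_variance", "tenengrad")) {
  measure <- match.arg(measure)
  n <- nrow(patch); m <- ncol(patch)
  if (n < 3L || m < 3L) stop("patch must be at least 3 x 3")
  ci <- 2:(n - 1L); cj <- 2:(m - 1L)
  if (measure == "laplacian_variance") {
    lap <- 4 * patch[ci, cj] - patch[ci - 1L, cj] - patch[ci + 1L, cj] -
      patch[ci, cj - 1L] - patch[ci, cj + 1L]
    v <- stats::var(as.vector(lap))
    if (is.na(v)) 0 else v
  } else {
    gx <- (patch[ci + 1L, cj - 1L] + 2 * patch[ci + 1L, cj] + patch[ci + 1L, cj + 1L]) -
          (patch[ci - 1L, cj - 1L] + 2 * patch[ci - 1L, cj] + patch[ci - 1L, cj + 1L])
    gy <- (patch[ci - 1L, cj + 1L] + 2 * patch[ci, cj + 1L] + patch[ci + 1L, cj + 1L]) -
          (patch[ci - 1L, cj - 1L] + 2 * patch[ci, cj - 1L] + patch[ci + 1L, cj - 1L])
    mean(gx^2 + gy^2)
  }
}

## k x k box sums over all fully-contained windows (valid region), via
## cumulative sums; returns a (nrow-k+1) x (ncol-k+1) matrix.
box_sum <- function(m, k) {
  cs <- rbind(0, apply(m, 2, cumsum))
  col <- cs[(k + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - k), , drop = FALSE]
  cs2 <- cbind(0, t(apply(col, 1, cumsum)))
  cs2[, (k + 1):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - k), drop = FALSE]
}

#' Structural similarity between two patches
#'
#' Standard SSIM with stabilising constants
#' \eqn{C_1 = (0.01 L)^2, C_2 = (0.03 L)^2}: the product
#' \eqn{((2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)) /
#'      ((\mu_a^2 + \mu_b^2 + C_1)(\sigma_a^2 + \sigma_b^2 + C_2))}
#' computed per sliding uniform window (population moments) and averaged.
#'
#' @param patch_a,patch_b numeric matrices of identical shape.
#' @param window_px odd window width, must not exceed either patch dimension.
#' @param dynamic_range intensity dynamic range \eqn{L} (1 for [0, 1] images).
#' @return Scalar in [-1, 1].
#' @export
ssim_score <- function(patch_a, patch_b, window_px = 7L, dynamic_range = 1) {
  if (!all(dim(patch_a) == dim(patch_b))) stop("patch shapes differ")
  k <- as.integer(window_px)
  if (k > nrow(patch_a) || k > ncol(patch_a))
    stop("SSIM window larger than patch")
  n2 <- k * k
  mu_a <- box_sum(patch_a, k) / n2
  mu_b <- box_sum(patch_b, k) / n2
  va <- box_sum(patch_a^2, k) / n2 - mu_a^2
  vb <- box_sum(patch_b^2, k) / n2 - mu_b^2
  cab <- box_sum(patch_a * patch_b, k) / n2 - mu_a * mu_b
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (pmax(va, 0) + pmax(vb, 0) + c2))
  mean(ssim_map)
}

#' Extract detected objects from per-layer masks
#'
#' For every labelled object in every layer: centroid, area, bounding box, a
#' padded intensity patch cropped from the layer, and a focus score.
#'
#' @param stack a \code{nuc_stack}.
#' @param masks list of \code{layer_mask}, one per layer, in layer order.
#' @param config a \code{\link{link_config}}.
#' @return List of detection records (lists with \code{layer}, \code{label},
#'   \code{x}, \code{y}, \code{area_px}, \code{bbox}, \code{focus},
#'   \code{patch}).
#' @export
detect_objects <- function(stack, masks, config = link_config()) {
  stopifnot(inherits(stack, "nuc_stack"))
  if (length(masks) != length(stack$layers))
    stop("need one mask per layer")
  pad <- config$patch_pad_px
  detections <- list()
  for (li in seq_along(masks)) {
    lab <- masks[[li]]$labels
    img <- stack$layers[[li]]
    nlab <- max(lab)
    if (nlab == 0L) next
    idx <- which(lab > 0L)
    labs <- lab[idx]
    xs <- (idx - 1L) %% nrow(lab) + 1L
    ys <- (idx - 1L) %/% nrow(lab) + 1L
    for (ob in seq_len(nlab)) {
      sel <- labs == ob
      ox <- xs[sel]; oy <- ys[sel]
      x0 <- max(1L, min(ox) - pad); x1 <- min(nrow(img), max(ox) + pad)
      y0 <- max(1L, min(oy) - pad); y1 <- min(ncol(img), max(oy) + pad)
      patch <- img[x0:x1, y0:y1, drop = FALSE]
      detections[[length(detections) + 1L]] <- list(
        layer = masks[[li]]$layer_index, label = ob,
        x = mean(ox), y = mean(oy), area_px = sum(sel),
        bbox = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
        focus = focus_score(patch, config$focus_measure),
        patch = patch)
    }
  }
  detections
}

## Resize a patch to a square comparison window and normalise to its maximum.
comparison_patch <- function(patch, patch_px) {
  r <- EBImage::imageData(EBImage::resize(EBImage::Image(patch),
                                          w = patch_px, h = patch_px))
  mx <- max(r)
  if (mx > 0) r / mx else r
}

#' Candidate links between detections across layers
#'
#' Builds the candidate-edge table used for deduplication: a pair of
#' detections in layers \code{l1 < l2} with
#' \code{l2 - l1 <= 1 + max_layer_gap} is a candidate when their centroids lie
#' within \code{max_centroid_shift_px} and the SSIM of their comparison
#' patches is at least \code{ssim_threshold}.
#'
#' @inheritParams detect_objects
#' @return List with \code{detections} (from \code{\link{detect_objects}})
#'   and \code{edges}, a data.frame \code{a, b, ssim, dist} of candidate links
#'   (indices into \code{detections}).
#' @export
link_candidates <- function(stack, masks, config = link_config()) {
  detections <- detect_objects(stack, masks, config)
  n <- length(detections)
  edges <- data.frame(a = integer(0), b = integer(0),
                      ssim = numeric(0), dist = numeric(0))
  if (n >= 2L) {
    cp <- lapply(detections, function(d) comparison_patch(d$patch, config$patch_px))
    layer <- vapply(detections, `[[`, 0L, "layer")
    xs <- vapply(detections, `[[`, 0, "x")
    ys <- vapply(detections, `[[`, 0, "y")
    ord <- order(layer, vapply(detections, `[[`, 0L, "label"))
    max_diff <- 1L + config$max_layer_gap
    for (ii in seq_len(n - 1L)) for (jj in (ii + 1L):n) {
      i <- ord[ii]; j <- ord[jj]
      dl <- layer[j] - layer[i]
      if (dl < 1L || dl > max_diff) next
      d <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2)
      if (d > config$max_centroid_shift_px) next
      s <- ssim_score(cp[[i]], cp[[j]], config$ssim_window_px)
      if (s >= config$ssim_threshold)
        edges <- rbind(edges, data.frame(a = i, b = j, ssim = s, dist = d))
    }
  }
  list(detections = detections, edges = edges)
}

## Exact maximum-total-SSIM chain partition of one connected component.
## Nodes are processed in (layer, label) order; each node either starts a new
## chain or extends a chain whose last node has a candidate edge to it.
## Extensions are explored best-SSIM-first (ties: smaller last-layer), and only
## strict improvements replace the incumbent, so among equal-score optima the
## documented tie-break (highest SSIM, then smaller layer index) wins.
solve_chains_exact <- function(nodes, layer, edge_w) {
  best <- list(score = -Inf, chains = NULL)
  nn <- length(nodes)
  recurse <- function(pos, chains, last_nodes, score) {
    if (pos > nn) {
      if (score > best$score + 1e-12) best <<- list(score = score, chains = chains)
      return(invisible(NULL))
    }
    v <- nodes[pos]
    opts <- list()
    for (ci in seq_along(chains)) {
      u <- last_nodes[ci]
      w <- edge_w[[paste(u, v)]]
      if (!is.null(w)) opts[[length(opts) + 1L]] <- list(ci = ci, w = w, ll = layer[u])
    }
    if (length(opts) > 0L) {
      o <- order(-vapply(opts, `[[`, 0, "w"), vapply(opts, `[[`, 0L, "ll"))
      for (k in o) {
        op <- opts[[k]]
        ch2 <- chains; ch2[[op$ci]] <- c(ch2[[op$ci]], v)
        ln2 <- last_nodes; ln2[op$ci] <- v
        recurse(pos + 1L, ch2, ln2, score + op$w)
      }
    }
    recurse(pos + 1L, c(chains, list(v)), c(last_nodes, v), score)
  }
  recurse(1L, list(), integer(0), 0)
  best$chains
}

## Greedy fallback for large components: per layer, accept candidate
## extensions in decreasing SSIM order (ties: smaller predecessor layer).
## `layer` is the global per-detection layer vector; edge endpoints are
## global detection indices.
solve_chains_greedy <- function(nodes, layer, edges) {
  chain_of <- rep(NA_integer_, max(nodes))
  chains <- list()
  last_of_chain <- integer(0)
  for (l in sort(unique(layer[nodes]))) {
    lv <- nodes[layer[nodes] == l]
    cand <- edges[edges$b %in% lv & !is.na(chain_of[edges$a]), , drop = FALSE]
    if (nrow(cand) > 0L) {
      cand <- cand[order(-cand$ssim, layer[cand$a]), , drop = FALSE]
      extended <- rep(FALSE, length(chains))
      for (r in seq_len(nrow(cand))) {
        v <- cand$b[r]
        if (!is.na(chain_of[v])) next
        ci <- chain_of[cand$a[r]]
        if (extended[ci] || last_of_chain[ci] != cand$a[r]) next
        chains[[ci]] <- c(chains[[ci]], v)
        last_of_chain[ci] <- v
        extended[ci] <- TRUE
        chain_of[v] <- ci
      }
    }
    for (v in lv) if (is.na(chain_of[v])) {
      chains[[length(chains) + 1L]] <- v
      last_of_chain[length(chains)] <- v
      chain_of[v] <- length(chains)
    }
  }
  chains
}

#' Deduplicate detections across layers and assign each nucleus to one layer
#'
#' Chains candidate-linked detections (see \code{\link{link_candidates}}) into
#' groups, one group per physical nucleus: within each connected component of
#' the candidate graph, the partition into layer-increasing chains maximising
#' total link SSIM is found exactly (branch-and-bound) for components of up to
#' \code{exact_limit} detections, and by a per-layer greedy best-match
#' otherwise. Ambiguities resolve by highest SSIM, then smaller layer index.
#' Each chain becomes one nucleus record assigned to its maximal-focus member
#' (tie: smaller layer); unmatched detections become singleton records.
#'
#' @inheritParams detect_objects
#' @param exact_limit component size up to which the chain partition is solved
#'   exactly.
#' @return A data.frame of class \code{nucleus_records} with columns
#'   \code{nucleus_id, assigned_layer, depth_um, x_px, y_px, area_px,
#'   axis_ratio, focus, n_member_layers}; the member detections of each record
#'   (data.frames of \code{layer, label}) are in \code{attr(x, "members")},
#'   and every detection appears in exactly one record.
#' @export
link_and_assign <- function(stack, masks, config = link_config(),
                            exact_limit = 12L) {
  lc <- link_candidates(stack, masks, config)
  detections <- lc$detections
  edges <- lc$edges
  n <- length(detections)
  if (n == 0L) return(empty_records(stack))
  layer <- vapply(detections, `[[`, 0L, "layer")

  # connected components over candidate edges (union-find)
  parent <- seq_len(n)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0L) for (r in seq_len(nrow(edges))) {
    ra <- find_root(edges$a[r]); rb <- find_root(edges$b[r])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(n), find_root, 0L)

  edge_w <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(edges) > 0L) for (r in seq_len(nrow(edges)))
    assign(paste(edges$a[r], edges$b[r]), edges$ssim[r], envir = edge_w)
  edge_lookup <- as.list(edge_w)

  chains <- list()
  for (cid in unique(comp)) {
    nodes <- which(comp == cid)
    nodes <- nodes[order(layer[nodes], vapply(detections[nodes], `[[`, 0L, "label"))]
    if (length(nodes) == 1L) {
      chains[[length(chains) + 1L]] <- nodes
    } else if (length(nodes) <= exact_limit) {
      sol <- solve_chains_exact(nodes, layer, edge_lookup)
      chains <- c(chains, sol)
    } else {
      sub <- edges[edges$a %in% nodes & edges$b %in% nodes, , drop = FALSE]
      chains <- c(chains, solve_chains_greedy(nodes, layer, sub))
    }
  }

  records_from_chains(chains, detections, masks, stack)
}

empty_records <- function(stack) {
  rec <- data.frame(nucleus_id = integer(0), assigned_layer = integer(0),
                    depth_um = numeric(0), x_px = numeric(0), y_px = numeric(0),
                    area_px = integer(0), axis_ratio = numeric(0),
                    focus = numeric(0), n_member_layers = integer(0))
  attr(rec, "members") <- list()
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

records_from_chains <- function(chains, detections, masks, stack) {
  nrec <- length(chains)
  rec <- data.frame(nucleus_id = seq_len(nrec),
                    assigned_layer = integer(nrec), depth_um = numeric(nrec),
                    x_px = numeric(nrec), y_px = numeric(nrec),
                    area_px = integer(nrec), axis_ratio = numeric(nrec),
                    focus = numeric(nrec), n_member_layers = integer(nrec))
  members <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    ch <- chains[[i]]
    foc <- vapply(detections[ch], `[[`, 0, "focus")
    lay <- vapply(detections[ch], `[[`, 0L, "layer")
    pick <- ch[order(-foc, lay)][1]
    d <- detections[[pick]]
    shp <- object_shape_from_mask(masks[[d$layer + 1L]]$labels, d$label,
                                  stack$pixel_size_um)
    rec$assigned_layer[i] <- d$layer
    rec$depth_um[i] <- d$layer * stack$layer_spacing_um
    rec$x_px[i] <- d$x; rec$y_px[i] <- d$y
    rec$area_px[i] <- d$area_px
    rec$axis_ratio[i] <- shp$axis_ratio
    rec$focus[i] <- d$focus
    rec$n_member_layers[i] <- length(ch)
    members[[i]] <- data.frame(layer = lay, label = vapply(detections[ch], `[[`, 0L, "label"))
  }
  ord <- order(rec$assigned_layer, rec$x_px, rec$y_px)
  rec <- rec[ord, , drop = FALSE]
  rec$nucleus_id <- seq_len(nrec)
  rownames(rec) <- NULL
  attr(rec, "members") <- members[ord]
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

#' Per-layer count profile from nucleus records
#'
#' \code{C_z} is the number of deduplicated nuclei assigned to each layer and
#' \code{C_summ} their total.
#'
#' @param records a \code{nucleus_records} data.frame.
#' @param n_layers number of layers in the stack.
#' @param layer_spacing_um z-step, microns.
#' @param day optional day label.
#' @return A \code{\link{count_profile}}.
#' @export
build_count_profile <- function(records, n_layers, layer_spacing_um = 7,
                                day = NA) {
  if (nrow(records) > 0 && any(records$assigned_layer >= n_layers))
    stop("assigned_layer out of range for n_layers = ", n_layers)
  counts <- tabulate(records$assigned_layer + 1L, nbins = n_layers)
  count_profile(counts, layer_spacing_um = layer_spacing_um, day = day)
}

#' Write the nucleus table as CSV
#'
#' Header: \code{nucleus_id,assigned_layer,depth_um,x_px,y_px,area_px,
#' axis_ratio,focus,n_member_layers}.
#'
#' @param records a \code{nucleus_records} data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_nucleus_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Score deduplicated records against generator ground truth
#'
#' Matches each record to the nearest ground-truth nucleus within
#' \code{max_match_dist_px} and reports recovery statistics: the fraction of
#' true nuclei recovered in their true layer, the worst per-layer count error
#' as a fraction of the true total, and how many true nuclei attracted more
#' than one record (duplicates).
#'
#' @param records a \code{nucleus_records} data.frame.
#' @param truth a \code{ground_truth} data.frame.
#' @param n_layers number of layers.
#' @param max_match_dist_px matching radius, px.
#' @return List with \code{n_truth}, \code{n_records}, \code{n_matched},
#'   \code{n_duplicated_truth}, \code{layer_accuracy},
#'   \code{max_layer_count_err_frac}, \code{counts}, \code{true_counts}.
#' @export
evaluate_against_truth <- function(records, truth, n_layers,
                                   max_match_dist_px = 18) {
  nt <- nrow(truth)
  nr <- nrow(records)
  match_of <- rep(NA_integer_, nr)
  if (nr > 0 && nt > 0) {
    for (i in seq_len(nr)) {
      d2 <- (truth$x_px - records$x_px[i])^2 + (truth$y_px - records$y_px[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_match_dist_px^2) match_of[i] <- j
    }
  }
  matched <- !is.na(match_of)
  correct_layer <- matched & records$assigned_layer == truth$layer[match_of]
  hit_counts <- tabulate(match_of[matched], nbins = nt)
  counts <- tabulate(records$assigned_layer + 1L, nbins = n_layers)
  true_counts <- attr(truth, "per_layer_counts")
  if (is.null(true_counts)) true_counts <- tabulate(truth$layer + 1L, nbins = n_layers)
  list(n_truth = nt, n_records = nr, n_matched = sum(matched),
       n_duplicated_truth = sum(hit_counts > 1L),
       layer_accuracy = if (nt > 0) sum(correct_layer) / nt else NA_real_,
       max_layer_count_err_frac = if (sum(true_counts) > 0)
         max(abs(counts - true_counts)) / sum(true_counts) else NA_real_,
       counts = counts, true_counts = true_counts)
}
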