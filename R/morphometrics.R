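## Nuclear shape statistics: moment-based ellipse fits, log-normal area
## distributions, and pairwise group comparisons.

#' Shape of one labelled object
#'
#' Computes area and the ellipse of equal second image moments: for a solid
#' ellipse with semi-axes \eqn{a \ge b}, the central second moments have
#' eigenvalues \eqn{a^2/4} and \eqn{b^2/4}, so the full axis lengths are
#' \eqn{4\sqrt{\lambda}}. A 1/12 px\eqn{^2} term corrects for pixel
#' discretisation. Degenerate objects (zero minor moment, e.g. a one-pixel
#' line) get their minor axis floored at one pixel and are flagged.
#'
#' @param labels integer label matrix.
#' @param label_id which object.
#' @param pixel_size_um lateral pixel size, microns.
#' @return List with \code{area_um2}, \code{major_um}, \code{minor_um} (full
#'   axis lengths), \code{axis_ratio} (major/minor, >= 1),
#'   \code{orientation_rad}, \code{centroid_px}, and \code{degenerate}.
#' @export
object_shape <- function(labels, label_id, pixel_size_um = 1) {
  idx <- which(labels == label_id)
  if (length(idx) < 5L) stop("object must have at least 5 pixels")
  object_shape_from_coords(
    x = (idx - 1L) %% nrow(labels) + 1L,
    y = (idx - 1L) %/% nrow(labels) + 1L,
    pixel_size_um = pixel_size_um)
}

## Same, from pixel coordinates; tolerant of small objects (used internally
## where a hard >= 5 px precondition would be unhelpful).
object_shape_from_coords <- function(x, y, pixel_size_um = 1) {
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)
  l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
  degenerate <- l2 < 1 / 12 + 1e-9
  major_px <- 4 * sqrt(l1)
  minor_px <- max(4 * sqrt(l2), if (degenerate) 1 else 0)
  v <- ev$vectors[, 1]
  list(area_um2 = n * pixel_size_um^2,
       major_um = major_px * pixel_size_um,
       minor_um = minor_px * pixel_size_um,
       axis_ratio = major_px / minor_px,
       orientation_rad = atan2(v[2], v[1]) %% pi,
       centroid_px = c(x = cx, y = cy),
       degenerate = degenerate)
}

object_shape_from_mask <- function(labels, label_id, pixel_size_um = 1) {
  idx <- which(labels == label_id)
  object_shape_from_coords((idx - 1L) %% nrow(labels) + 1L,
                           (idx - 1L) %/% nrow(labels) + 1L,
                           pixel_size_um)
}

#' Shape table for every object in a labelled mask
#'
#' @param labels integer label matrix (0 = background).
#' @param pixel_size_um lateral pixel size, microns.
#' @return data.frame with one row per label: \code{label, area_um2, major_um,
#'   minor_um, axis_ratio, orientation_rad, degenerate}.
#' @export
shape_table <- function(labels, pixel_size_um = 1) {
  nlab <- max(labels)
  rows <- vector("list", nlab)
  for (i in seq_len(nlab)) {
    s <- object_shape_from_mask(labels, i, pixel_size_um)
    rows[[i]] <- data.frame(label = i, area_um2 = s$area_um2,
                            major_um = s$major_um, minor_um = s$minor_um,
                            axis_ratio = s$axis_ratio,
                            orientation_rad = s$orientation_rad,
                            degenerate = s$degenerate)
  }
  if (nlab == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      major_um = numeric(0), minor_um = numeric(0),
                      axis_ratio = numeric(0), orientation_rad = numeric(0),
                      degenerate = logical(0)))
  do.call(rbind, rows)
}

#' A named morphometric sample
#'
#' @param group group label (e.g. a mat composition or transduction arm).
#' @param areas nuclear areas, square microns (> 0).
#' @param axis_ratios major-to-minor axis ratios (>= 1); optional.
#' @param day observation day; optional.
#' @return Object of class \code{morph_sample}.
#' @export
morph_sample <- function(group, areas, axis_ratios = NULL, day = NA) {
  if (any(areas <= 0)) stop("areas must be positive")
  if (!is.null(axis_ratios) && any(axis_ratios < 1))
    stop("axis ratios must be >= 1")
  structure(list(group = as.character(group), day = day, areas = areas,
                 axis_ratios = axis_ratios),
            class = "morph_sample")
}

#' Maximum-likelihood log-normal fit
#'
#' Fits meanlog/sdlog by maximum likelihood (via \pkg{fitdistrplus}) and
#' reports the Kolmogorov-Smirnov statistic of the fitted distribution as a
#' goodness-of-fit measure. Nuclear areas in large fields are classically
#' log-normal, so this is the package's reference distribution for area data.
#'
#' @param values positive values (>= 10 of them).
#' @return List with \code{mu} (meanlog), \code{sigma} (sdlog), \code{gof_ks}
#'   (KS statistic), and \code{n}.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 10L) stop("need at least 10 values")
  if (any(values <= 0)) stop("values must be positive")
  if (stats::sd(log(values)) < 1e-12) {
    # degenerate: all values (essentially) equal
    return(list(mu = mean(log(values)), sigma = 0, gof_ks = 0,
                n = length(values)))
  }
  fit <- fitdistrplus::fitdist(values, "lnorm")
  ks <- suppressWarnings(stats::ks.test(values, "plnorm",
                                        meanlog = fit$estimate["meanlog"],
                                        sdlog = fit$estimate["sdlog"]))
  list(mu = unname(fit$estimate["meanlog"]),
       sigma = unname(fit$estimate["sdlog"]),
       gof_ks = unname(ks$statistic), n = length(values))
}

#' All-pairs group comparison of a morphometric quantity
#'
#' \code{pairwise_mean_difference}: one-way ANOVA followed by Tukey's honest
#' significant difference, reporting the mean difference and family-wise
#' adjusted p per pair. \code{paired_rank}: Friedman rank test across matched
#' samples (equal lengths, e.g. repeated days) with pairwise paired Wilcoxon
#' tests, Holm-adjusted. Significance is called at 0.05.
#'
#' @param samples list of \code{\link{morph_sample}} objects (>= 2 groups).
#' @param mode comparison mode.
#' @param value which stored quantity to compare.
#' @return data.frame with columns \code{pair, statistic, p_adj, significant};
#'   for \code{paired_rank} the overall Friedman test is in
#'   \code{attr(x, "overall")}.
#' @export
compare_groups <- function(samples,
                           mode = c("pairwise_mean_difference", "paired_rank"),
                           value = c("areas", "axis_ratios")) {
  mode <- match.arg(mode)
  value <- match.arg(value)
  if (length(samples) < 2L) stop("need at least 2 groups")
  vals <- lapply(samples, function(s) {
    v <- s[[value]]
    if (is.null(v) || length(v) < 2L)
      stop("group '", s$group, "' has fewer than 2 observations")
    v
  })
  groups <- vapply(samples, `[[`, "", "group")
  if (anyDuplicated(groups)) stop("group labels must be unique")

  if (mode == "pairwise_mean_difference") {
    df <- data.frame(value = unlist(vals),
                     group = factor(rep(groups, lengths(vals)), levels = groups))
    tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
    out <- data.frame(pair = rownames(tk), statistic = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05)
    rownames(out) <- NULL
    attr(out, "overall") <- NULL
    out
  } else {
    ns <- lengths(vals)
    if (length(unique(ns)) != 1L)
      stop("paired_rank requires equal-length matched samples")
    m <- do.call(cbind, vals)
    colnames(m) <- groups
    overall <- stats::friedman.test(m)
    combs <- utils::combn(seq_along(groups), 2)
    stat <- p <- numeric(ncol(combs))
    pair <- character(ncol(combs))
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      w <- suppressWarnings(stats::wilcox.test(m[, i], m[, j], paired = TRUE,
                                               exact = FALSE))
      stat[k] <- unname(w$statistic)
      p[k] <- w$p.value
      pair[k] <- paste0(groups[j], "-", groups[i])
    }
    p_adj <- stats::p.adjust(p, method = "holm")
    out <- data.frame(pair = pair, statistic = stat, p_adj = p_adj,
                      significant = p_adj < 0.05)
    attr(out, "overall") <- overall
    out
  }
}
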