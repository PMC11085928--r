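## Depth-colonisation kinetics: conversion curves alpha(z), exponential and
## Hill model fits, proliferation rates, and the migration-activity statistic
## (alpha / z^2) x (C_summ / t_d) with its linear-fit slope.

#' Per-layer count profile
#'
#' \code{C_z}, the number of nuclei counted in each layer (layer 0 at the
#' seeding surface), plus their total \code{C_summ}.
#'
#' @param counts non-negative integer vector, one count per layer.
#' @param layer_spacing_um z-step between layers, microns.
#' @param day optional day label.
#' @return Object of class \code{count_profile}: list with \code{counts},
#'   \code{C_summ}, \code{n_layers}, \code{layer_spacing_um}, \code{day}.
#' @export
count_profile <- function(counts, layer_spacing_um = 7, day = NA) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) stop("counts must be integers")
  structure(list(counts = as.integer(round(counts)),
                 C_summ = as.integer(round(sum(counts))),
                 n_layers = length(counts),
                 layer_spacing_um = layer_spacing_um,
                 day = day),
            class = "count_profile")
}

#' @export
print.count_profile <- function(x, ...) {
  cat(sprintf("count_profile: %d layers, C_summ = %d%s\n", x$n_layers,
              x$C_summ, if (is.na(x$day)) "" else sprintf(", day %s", x$day)))
  cat("  C_z:", x$counts, "\n")
  invisible(x)
}

#' Write/read count profiles as CSV
#'
#' Schema: \code{day,layer,count} with 0-based layers.
#'
#' @param profiles list of \code{count_profile} (or a single one).
#' @param path file path.
#' @return \code{path} invisibly (write); list of profiles (read).
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "count_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(day = p$day, layer = seq_len(p$n_layers) - 1L, count = p$counts))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param layer_spacing_um z-step to attach to the profiles read back.
#' @export
read_profile_csv <- function(path, layer_spacing_um = 7) {
  df <- utils::read.csv(path)
  stopifnot(all(c("day", "layer", "count") %in% names(df)))
  lapply(split(df, df$day), function(d) {
    d <- d[order(d$layer), ]
    count_profile(d$count, layer_spacing_um = layer_spacing_um,
                  day = d$day[1])
  })
}

#' Conversion curve of a count profile
#'
#' The conversion value \eqn{\alpha(z)} is the cumulative fraction of all
#' counted cells lying at or above depth \eqn{z}: for layer \eqn{k} (0-based),
#' \eqn{\alpha_k = \sum_{j \le k} C_j / C_{summ}}, reported at the layer's
#' lower-boundary depth \eqn{z_k = (k+1) \times} spacing, since the cumulative
#' count through a layer includes everything down to its bottom boundary. The
#' per-layer fractions \eqn{C_z / C_{summ}} are reported alongside.
#'
#' @param profile a \code{\link{count_profile}} with \code{C_summ > 0}.
#' @return Object of class \code{conversion_curve}: list with \code{z_um},
#'   \code{alpha} (non-decreasing, ending at 1), \code{fraction},
#'   \code{layer_spacing_um}, \code{day}.
#' @export
conversion_curve <- function(profile) {
  stopifnot(inherits(profile, "count_profile"))
  if (profile$C_summ == 0) stop("empty profile: C_summ = 0")
  frac <- profile$counts / profile$C_summ
  structure(list(z_um = seq_len(profile$n_layers) * profile$layer_spacing_um,
                 alpha = cumsum(frac),
                 fraction = frac,
                 layer_spacing_um = profile$layer_spacing_um,
                 day = profile$day),
            class = "conversion_curve")
}

#' Fit a kinetic model to a conversion curve
#'
#' Least-squares fits of the three colonisation regimes:
#' \itemize{
#'   \item \code{surface_exponential}: \eqn{\alpha(z) = 1 - e^{-kz}} -- cells
#'     settle at the seeding surface;
#'   \item \code{depth_exponential}: \eqn{\alpha(z) = \max(0,
#'     1 - e^{-k(z - z_0)})} -- the same law with the mass shifted below
#'     depth \eqn{z_0};
#'   \item \code{hill}: \eqn{\alpha(z) = z^n / (K^n + z^n)} -- sigmoidal
#'     colonisation with half-depth \eqn{K} and cooperativity \eqn{n}.
#' }
#' \code{model = "best"} fits all three and keeps the converged fit with the
#' smallest residual sum of squares. Fitting uses Levenberg-Marquardt
#' (\pkg{minpack.lm}) with starts \eqn{K} = median depth, \eqn{n} = 2,
#' \eqn{k} = 1/median depth; non-convergence is reported via the
#' \code{converged} flag, never silently.
#'
#' The deepest point of a conversion curve is excluded from fitting: by
#' normalisation \eqn{\alpha = 1} at the last layer whatever the colonisation
#' law (the material's deepest layer absorbs all remaining cells), so that
#' point is a closure constraint, not data, and including it biases the fit
#' whenever the scaffold truncates the depth distribution's tail.
#'
#' @param curve a \code{\link{conversion_curve}} with >= 4 points.
#' @param model model name or \code{"best"}.
#' @return Object of class \code{kinetic_fit}: list with \code{model},
#'   \code{params}, \code{rss}, \code{converged}, \code{fitted},
#'   \code{n_points}, and (for \code{"best"}) \code{candidates}, the RSS of
#'   every converged candidate.
#' @export
fit_conversion_model <- function(curve,
                                 model = c("best", "hill",
                                           "surface_exponential",
                                           "depth_exponential")) {
  stopifnot(inherits(curve, "conversion_curve"))
  model <- match.arg(model)
  if (any(curve$alpha < -1e-9 | curve$alpha > 1 + 1e-9))
    stop("alpha must lie in [0, 1]")
  # drop the closure point (see Details)
  np <- length(curve$z_um)
  z <- curve$z_um[-np]; a <- curve$alpha[-np]
  if (length(z) < 4L)
    stop("need at least 4 points to fit (after dropping the closure point)")

  fit_one <- function(m) {
    res <- switch(m,
      hill = try_nls(a ~ z^n / (K^n + z^n),
                     list(n = 2, K = stats::median(z)),
                     lower = c(n = 1e-6, K = 1e-6), z = z, a = a),
      surface_exponential = try_nls(a ~ 1 - exp(-k * z),
                                    list(k = 1 / stats::median(z)),
                                    lower = c(k = 1e-9), z = z, a = a),
      depth_exponential = try_nls(a ~ pmax(0, 1 - exp(-k * (z - z0))),
                                  list(k = 1 / stats::median(z),
                                       z0 = z[max(1, which(a > 0.05)[1]) ] / 2),
                                  lower = c(k = 1e-9, z0 = 0), z = z, a = a))
    structure(c(list(model = m, n_points = length(z)), res),
              class = "kinetic_fit")
  }

  if (model != "best") return(fit_one(model))
  cands <- lapply(c("hill", "surface_exponential", "depth_exponential"),
                  fit_one)
  ok <- vapply(cands, `[[`, TRUE, "converged")
  if (!any(ok)) {
    best <- cands[[1]]
    best$converged <- FALSE
    return(best)
  }
  rss <- vapply(cands, function(f) if (f$converged) f$rss else Inf, 0)
  best <- cands[[which.min(rss)]]
  best$candidates <- stats::setNames(rss, vapply(cands, `[[`, "", "model"))
  best
}

try_nls <- function(formula, start, lower, z, a) {
  env <- new.env()
  assign("z", z, env); assign("a", a, env)
  environment(formula) <- env
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(params = unlist(start), rss = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(z)),
                diagnostic = conditionMessage(fit)))
  list(params = coef(fit), rss = sum(stats::residuals(fit)^2),
       converged = TRUE, fitted = as.numeric(stats::fitted(fit)),
       diagnostic = NULL)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit: %s (%s), RSS = %s\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              format(x$rss, digits = 4)))
  print(x$params)
  invisible(x)
}

#' Proliferation rates over the study intervals
#'
#' The rate over an interval is the total cell count at the interval's end
#' divided by the interval length in days, \eqn{C_{summ} / t_d}. The default
#' intervals are repopulation to day 1 (\code{t_1}, 1 day), day 1 to day 4
#' (\code{t_2}, 3 days), and day 4 to day 7 (\code{t_3}, 3 days).
#'
#' @param profiles_by_day list of \code{\link{count_profile}} objects with
#'   \code{day} set.
#' @param intervals data.frame with columns \code{name}, \code{end_day},
#'   \code{duration_days}.
#' @return data.frame \code{name, end_day, duration_days, C_summ,
#'   rate_cells_per_day}.
#' @export
proliferation_rate <- function(profiles_by_day,
                               intervals = data.frame(
                                 name = c("t_1", "t_2", "t_3"),
                                 end_day = c(1, 4, 7),
                                 duration_days = c(1, 3, 3))) {
  if (length(profiles_by_day) < 2L) stop("need profiles for at least two days")
  if (any(intervals$duration_days <= 0)) stop("intervals must be positive")
  days <- vapply(profiles_by_day, `[[`, 0, "day")
  rate <- numeric(nrow(intervals))
  csumm <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    j <- which(days == intervals$end_day[i])
    if (length(j) == 0L)
      stop("missing count profile for day ", intervals$end_day[i])
    csumm[i] <- profiles_by_day[[j[1]]]$C_summ
    rate[i] <- csumm[i] / intervals$duration_days[i]
  }
  data.frame(name = intervals$name, end_day = intervals$end_day,
             duration_days = intervals$duration_days, C_summ = csumm,
             rate_cells_per_day = rate)
}

#' Migration-activity curve and slope
#'
#' For conversion steps \eqn{\alpha \in \{0.1, ..., 0.9\}}, the depth
#' \eqn{z(\alpha)} is read off the conversion curve by monotone
#' piecewise-linear interpolation (the point (0, 0) is prepended; a flat
#' segment spanning a requested \eqn{\alpha} resolves to the segment midpoint
#' and is flagged). The migration activity at each step is
#' \eqn{(\alpha / z(\alpha)^2) \times rate}, with \eqn{rate = C_{summ}/t_d}
#' the proliferation rate, and the reported slope is the coefficient of an
#' ordinary least-squares line through the activity-vs-\eqn{\alpha} points:
#' the migration-activity tangent \eqn{(1/z^2)(C_{summ}/t_d)}.
#'
#' @param curve a \code{\link{conversion_curve}}.
#' @param rate proliferation rate, cells/day.
#' @param alpha_steps strictly increasing conversion steps in (0, 1).
#' @return Object of class \code{migration_activity}: list with \code{alpha},
#'   \code{z_um}, \code{activity}, \code{rate}, \code{slope},
#'   \code{intercept}, \code{flagged}.
#' @export
migration_activity_curve <- function(curve, rate,
                                     alpha_steps = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(curve, "conversion_curve"))
  if (rate < 0) stop("rate must be >= 0")
  if (any(diff(alpha_steps) <= 0)) stop("alpha_steps must be strictly increasing")
  if (any(alpha_steps <= 0 | alpha_steps >= 1)) stop("alpha_steps must be in (0, 1)")
  az <- c(0, curve$alpha)
  zz <- c(0, curve$z_um)
  zi <- numeric(length(alpha_steps))
  flagged <- logical(length(alpha_steps))
  tol <- 1e-9
  for (k in seq_along(alpha_steps)) {
    a <- alpha_steps[k]
    if (a > max(az) + tol)
      stop("conversion curve never reaches alpha = ", a)
    i <- which(az >= a - tol)[1]
    if (abs(az[i] - a) <= tol) {
      # grid hit; if the curve is flat at this alpha, take the segment
      # midpoint and flag the point
      j <- i
      while (j < length(az) && abs(az[j + 1] - a) <= tol) j <- j + 1
      if (j > i) {
        zi[k] <- (zz[i] + zz[j]) / 2
        flagged[k] <- TRUE
      } else {
        zi[k] <- zz[i]
      }
    } else {
      # strictly bracketed: az[i-1] < a < az[i]
      zi[k] <- zz[i - 1] + (a - az[i - 1]) / (az[i] - az[i - 1]) *
        (zz[i] - zz[i - 1])
    }
  }
  activity <- alpha_steps / zi^2 * rate
  fit <- stats::lm(activity ~ alpha_steps)
  structure(list(alpha = alpha_steps, z_um = zi, activity = activity,
                 rate = rate, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), flagged = flagged),
            class = "migration_activity")
}

#' @export
print.migration_activity <- function(x, ...) {
  cat(sprintf("migration_activity: rate %.3g cells/day, slope %.4g\n",
              x$rate, x$slope))
  print(data.frame(alpha = x$alpha, z_um = x$z_um, activity = x$activity))
  invisible(x)
}

#' Share of migration activity carried by the shallowest cell fraction
#'
#' Trapezoidal area under the activity-vs-\eqn{\alpha} curve for
#' \eqn{\alpha \le} \code{cell_fraction}, as a fraction of the total area over
#' the full \eqn{\alpha} grid. Answers questions of the form "what share of
#' the migration activity do the first half of the cells account for?".
#'
#' @param activity a \code{\link{migration_activity}} with >= 2 points.
#' @param cell_fraction fraction of cells in (0, 1].
#' @return Scalar share in [0, 1].
#' @export
activity_share <- function(activity, cell_fraction) {
  stopifnot(inherits(activity, "migration_activity"))
  if (length(activity$alpha) < 2L) stop("need at least 2 activity points")
  if (cell_fraction <= 0 || cell_fraction > 1)
    stop("cell_fraction must be in (0, 1]")
  a <- activity$alpha; y <- activity$activity
  total <- trapz(a, y)
  if (cell_fraction <= a[1]) return(0)
  if (cell_fraction >= a[length(a)]) return(1)
  yf <- stats::approx(a, y, xout = cell_fraction)$y
  keep <- a < cell_fraction
  part <- trapz(c(a[keep], cell_fraction), c(y[keep], yf))
  part / total
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
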