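## End-to-end orchestration: stack in -> nucleus CSV, count profile, kinetic
## fits and activity report out, with per-stage logging.

#' Read a nuclei z-stack
#'
#' Multi-page TIFF: one layer per page, page 0 first. PNG directory: one
#' layer per file, lexicographic filename order. Multi-channel pages are
#' reduced to their first channel. All layers must share one size.
#'
#' @param path file (TIFF) or directory (PNGs).
#' @param format \code{"auto"} (by extension), \code{"multipage_tiff"} or
#'   \code{"png_dir"}.
#' @param layer_spacing_um,pixel_size_um physical calibration attached to the
#'   stack (configuration is authoritative; these formats carry none).
#' @return A \code{nuc_stack}.
#' @export
read_stack <- function(path, format = c("auto", "multipage_tiff", "png_dir"),
                       layer_spacing_um = 7, pixel_size_um = 0.5) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "png_dir" else "multipage_tiff"
  if (format == "multipage_tiff") {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 0L) stop("stack has zero layers: ", path)
    layers <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      t(p)  # row-major image -> [x, y]
    })
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG layers in ", path)
    layers <- lapply(files, function(f) {
      p <- png::readPNG(f)
      if (length(dim(p)) == 3L) p <- p[, , 1]
      t(p)
    })
  }
  dims <- vapply(layers, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0L)
    stop("layer ", bad[1] - 1L, " has dimensions ",
         paste(dims[, bad[1]], collapse = "x"), " but layer 0 has ",
         paste(dims[, 1], collapse = "x"))
  new_nuc_stack(layers, layer_spacing_um, pixel_size_um)
}

#' Pipeline run configuration
#'
#' @param input a \code{nuc_stack}, or a path understood by
#'   \code{\link{read_stack}}.
#' @param format stack format for path inputs.
#' @param layer_spacing_um,pixel_size_um physical calibration.
#' @param seg a \code{\link{seg_config}}.
#' @param link a \code{\link{link_config}}.
#' @param day day label for the resulting count profile.
#' @param t_d interval length in days used for the proliferation rate
#'   \code{C_summ / t_d}.
#' @param kinetic_model model passed to \code{\link{fit_conversion_model}}.
#' @param out_dir output directory (created if missing).
#' @param make_plots write profile/conversion/activity PNG plots.
#' @param seed integer seed (the classical path is deterministic; the seed
#'   fixes any stochastic extension).
#' @param verbose log progress to stderr.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(input, format = "auto", layer_spacing_um = 7,
                       pixel_size_um = 0.5, seg = seg_config(),
                       link = link_config(), day = 1, t_d = 1,
                       kinetic_model = "best", out_dir = tempfile("nucstack_"),
                       make_plots = TRUE, seed = 1L, verbose = TRUE) {
  if (is.character(input) && !file.exists(input) && !dir.exists(input))
    stop("input path does not exist: ", input)
  structure(list(input = input, format = format,
                 layer_spacing_um = layer_spacing_um,
                 pixel_size_um = pixel_size_um, seg = seg, link = link,
                 day = day, t_d = t_d, kinetic_model = kinetic_model,
                 out_dir = out_dir, make_plots = isTRUE(make_plots),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

pipeline_log <- function(config, log_path, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  if (config$verbose) message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full migration-quantification pipeline
#'
#' Stages: read/ingest stack, segment every layer (tiled when a layer exceeds
#' the configured tile size), deduplicate and assign nuclei across layers,
#' morphometrics, per-layer counting, conversion-curve fit and
#' migration-activity transform. Writes \code{nuclei.csv},
#' \code{profile.csv}, \code{fits.json}, \code{activity.csv},
#' \code{summary.json}, \code{run.log} (and plot PNGs) under
#' \code{config$out_dir}. An empty stack yields zero-count outputs and skips
#' the kinetics with a logged reason, without error. With a fixed
#' configuration the classical path writes identical outputs on every run.
#'
#' @param config a \code{\link{run_config}}.
#' @return Run summary (list) with per-stage object counts, the records, the
#'   profile, and (when computed) the kinetic fit and activity, invisibly
#'   mirrored in \code{summary.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  stage <- "ingest"
  result <- tryCatch({
    stack <- if (inherits(config$input, "nuc_stack")) config$input
             else read_stack(config$input, config$format,
                             config$layer_spacing_um, config$pixel_size_um)
    stack$layer_spacing_um <- config$layer_spacing_um
    stack$pixel_size_um <- config$pixel_size_um
    nl <- length(stack$layers)
    pipeline_log(config, log_path, stage, sprintf("%d layers", nl))

    stage <- "segment"
    masks <- segment_stack(stack, config$seg)
    n_det <- sum(vapply(masks, `[[`, 0L, "n_objects"))
    pipeline_log(config, log_path, stage, sprintf("%d raw detections", n_det))

    stage <- "link"
    records <- link_and_assign(stack, masks, config$link)
    pipeline_log(config, log_path, stage,
                 sprintf("%d nuclei after deduplication", nrow(records)))
    write_nucleus_csv(records, file.path(config$out_dir, "nuclei.csv"))

    stage <- "profile"
    profile <- build_count_profile(records, nl, config$layer_spacing_um,
                                   day = config$day)
    write_profile_csv(profile, file.path(config$out_dir, "profile.csv"))
    pipeline_log(config, log_path, stage,
                 sprintf("C_summ = %d", profile$C_summ))

    summary <- list(n_layers = nl, n_detections = n_det,
                    n_nuclei = nrow(records), C_summ = profile$C_summ,
                    day = config$day, t_d = config$t_d)

    stage <- "kinetics"
    if (profile$C_summ > 0) {
      curve <- conversion_curve(profile)
      fit <- fit_conversion_model(curve, config$kinetic_model)
      rate <- profile$C_summ / config$t_d
      act <- migration_activity_curve(curve, rate)
      utils::write.csv(data.frame(alpha = act$alpha, z_um = act$z_um,
                                  activity = act$activity,
                                  flagged = act$flagged),
                       file.path(config$out_dir, "activity.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(model = fit$model, params = as.list(fit$params), rss = fit$rss,
             converged = fit$converged, rate_cells_per_day = rate,
             activity_slope = act$slope),
        file.path(config$out_dir, "fits.json"), auto_unbox = TRUE,
        digits = NA)
      pipeline_log(config, log_path, stage,
                   sprintf("model %s, activity slope %.4g", fit$model,
                           act$slope))
      if (config$make_plots) plot_pipeline(profile, curve, act, config$out_dir)
      summary <- c(summary, list(kinetic_model = fit$model,
                                 kinetic_params = as.list(fit$params),
                                 kinetic_converged = fit$converged,
                                 rate_cells_per_day = rate,
                                 activity_slope = act$slope))
      summary$curve <- curve; summary$fit <- fit; summary$activity <- act
    } else {
      pipeline_log(config, log_path, stage,
                   "skipped: empty profile (C_summ = 0)")
      summary$kinetics_skipped <- "empty profile (C_summ = 0)"
    }
    summary$records <- records
    summary$profile <- profile
    summary
  }, error = function(e) {
    pipeline_log(config, log_path, stage, paste("FAILED:", conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs in ", config$out_dir, ")", call. = FALSE)
  })

  json_safe <- result[!vapply(result, function(x)
    inherits(x, c("nucleus_records", "count_profile", "conversion_curve",
                  "kinetic_fit", "migration_activity")), TRUE)]
  jsonlite::write_json(json_safe, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

## Base-graphics renderings of the three standard panels.
plot_pipeline <- function(profile, curve, activity, out_dir) {
  grDevices::png(file.path(out_dir, "profile.png"), 600, 450)
  graphics::barplot(profile$counts / profile$C_summ,
                    names.arg = seq_len(profile$n_layers) - 1L,
                    xlab = "layer (z)", ylab = expression(C[z] / C[summ]),
                    main = "Per-layer cell fraction")
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "conversion.png"), 600, 450)
  graphics::plot(curve$z_um, curve$alpha, type = "b", pch = 16,
                 xlab = "depth z (um)", ylab = expression(alpha),
                 ylim = c(0, 1), main = "Conversion curve")
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "activity.png"), 600, 450)
  graphics::plot(activity$alpha, activity$activity, type = "b", pch = 16,
                 xlab = expression(alpha),
                 ylab = expression((alpha / z^2) %*% (C[summ] / t[d])),
                 main = sprintf("Migration activity (slope %.3g)",
                                activity$slope))
  graphics::abline(activity$intercept, activity$slope, lty = 2)
  grDevices::dev.off()
}
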