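test_that("moment ellipse matches analytic shapes", {
  m <- ellipse_mask(64, 48, 32, 24, 10, 5)          # semi-axes 10, 5 px
  s <- object_shape(m, 1L, pixel_size_um = 1)
  expect_equal(s$area_um2, pi * 10 * 5, tolerance = 0.05)
  expect_equal(s$axis_ratio, 2, tolerance = 0.05)
  expect_equal(s$major_um, 20, tolerance = 0.05 * 20)
  expect_false(s$degenerate)

  disk <- ellipse_mask(40, 40, 20, 20, 9, 9)
  sd_ <- object_shape(disk, 1L)
  expect_equal(sd_$axis_ratio, 1, tolerance = 0.02)
})

test_that("shape is invariant to rotation and translation", {
  # semi-axes 16 x 8 px: large enough that discretisation jitter is ~1%
  ref <- object_shape(ellipse_mask(100, 100, 50, 50, 16, 8), 1L)
  for (th in c(pi / 7, pi / 3, 2.1)) {
    rot <- object_shape(ellipse_mask(100, 100, 47, 54, 16, 8, th), 1L)
    # both renders sit within discretisation error of the analytic values
    expect_equal(rot$area_um2, pi * 16 * 8, tolerance = 0.03)
    expect_equal(ref$area_um2, pi * 16 * 8, tolerance = 0.03)
    expect_equal(rot$axis_ratio, ref$axis_ratio, tolerance = 0.03)
  }
})

test_that("moment axes agree with EBImage's moment features", {
  m <- ellipse_mask(100, 100, 50, 50, 15, 8, pi / 5)
  ours <- object_shape(m, 1L)
  eb <- EBImage::computeFeatures.moment(EBImage::Image(m))
  expect_equal(ours$major_um, unname(eb[1, "m.majoraxis"]), tolerance = 0.02)
  # minor from eccentricity: b = a * sqrt(1 - e^2)
  eb_minor <- eb[1, "m.majoraxis"] * sqrt(1 - eb[1, "m.eccentricity"]^2)
  expect_equal(ours$minor_um, unname(eb_minor), tolerance = 0.02)
})

test_that("degenerate objects are floored and flagged", {
  line <- matrix(0L, 20, 20); line[5:14, 7] <- 1L
  s <- object_shape(line, 1L)
  expect_true(s$degenerate)
  expect_gte(s$minor_um, 1)
  expect_true(is.finite(s$axis_ratio))
  tiny <- matrix(0L, 5, 5); tiny[2:3, 2] <- 1L
  expect_error(object_shape(tiny, 1L), "at least 5 pixels")
})

test_that("shape_table covers all labels with pixel calibration", {
  p <- stack_params(n_layers = 2, width_px = 192, height_px = 192,
                    pixel_size_um = 0.5, n_nuclei = 3, seed = 6)
  pr <- generate_training_pairs(p, 1)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pr[[1]]$mask)))
  storage.mode(lab) <- "integer"
  tb <- shape_table(lab, pixel_size_um = 0.5)
  expect_equal(nrow(tb), 3)
  expect_true(all(tb$axis_ratio >= 1))
  # area in um2 = px count * 0.25
  expect_equal(tb$area_um2, vapply(1:3, function(i) sum(lab == i) * 0.25, 0))
})

test_that("log-normal fits recover their parameters", {
  set.seed(11)
  x <- rlnorm(15000, meanlog = 4, sdlog = 0.3)
  f <- fit_lognormal(x)
  expect_equal(f$mu, 4, tolerance = 0.02 / 4)
  expect_equal(f$sigma, 0.3, tolerance = 0.02 / 0.3)
  expect_lt(f$gof_ks, 0.02)

  # scaling by c shifts mu by log(c), sigma unchanged
  f2 <- fit_lognormal(3 * x)
  expect_equal(f2$mu - f$mu, log(3), tolerance = 1e-6)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)

  fc <- fit_lognormal(rep(5, 50))
  expect_equal(fc$sigma, 0)
  expect_equal(fc$mu, log(5))

  expect_error(fit_lognormal(c(-1, rep(2, 20))), "positive")
  expect_error(fit_lognormal(1:5), "at least 10")
})

test_that("parameter recovery improves with sample size on average", {
  err_at <- function(n) {
    mean(vapply(1:8, function(s) {
      set.seed(1000 + s)
      abs(fit_lognormal(rlnorm(n, 4, 0.3))$mu - 4)
    }, 0))
  }
  errs <- c(err_at(100), err_at(1000), err_at(15000))
  expect_true(all(diff(errs) < 0))
})

test_that("Tukey comparisons detect large shifts and respect the null", {
  set.seed(20)
  null_hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    a <- morph_sample("A", rnorm(500, 100, 10))
    b <- morph_sample("B", rnorm(500, 100, 10))
    any(compare_groups(list(a, b))$significant)
  }, TRUE)
  expect_gte(mean(!null_hits), 0.9)

  set.seed(21)
  big <- compare_groups(list(morph_sample("A", rnorm(100, 100, 10)),
                             morph_sample("B", rnorm(100, 130, 10))))
  expect_true(big$significant)
  expect_equal(big$statistic, 30, tolerance = 0.2)

  # a group against a copy of itself: zero difference, not significant
  set.seed(22)
  x <- rnorm(200, 50, 5)
  self <- compare_groups(list(morph_sample("A", x), morph_sample("A2", x)))
  expect_equal(self$statistic, 0)
  expect_false(self$significant)
})

test_that("paired rank mode runs Friedman plus pairwise Wilcoxon", {
  set.seed(30)
  base <- rnorm(40, 100, 5)
  s1 <- morph_sample("d1", base)
  s2 <- morph_sample("d4", base + rnorm(40, 8, 2))   # clear paired shift
  s3 <- morph_sample("d7", base + rnorm(40, 16, 2))
  res <- compare_groups(list(s1, s2, s3), mode = "paired_rank")
  expect_equal(nrow(res), 3)
  expect_true(all(res$significant))
  expect_s3_class(attr(res, "overall"), "htest")
  expect_lt(attr(res, "overall")$p.value, 0.01)

  expect_error(compare_groups(list(s1, morph_sample("x", runif(10, 50, 99))),
                              mode = "paired_rank"), "equal-length")
  expect_error(compare_groups(list(s1), mode = "paired_rank"), "at least 2")
  expect_error(compare_groups(list(s1, morph_sample("y", 5))),
               "fewer than 2")
})
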