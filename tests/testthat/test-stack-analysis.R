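test_that("focus scores behave like sharpness measures", {
  expect_identical(focus_score(matrix(0.5, 9, 9)), 0)
  expect_identical(focus_score(matrix(0.5, 9, 9), "tenengrad"), 0)

  sharp <- 0.9 * ellipse_mask(41, 41, 21, 21, 12, 8)
  blurred <- EBImage::imageData(EBImage::gblur(EBImage::Image(sharp), 2))
  for (meas in c("laplacian_variance", "tenengrad")) {
    fs <- focus_score(sharp, meas)
    fb <- focus_score(blurred, meas)
    expect_gt(fs, fb)
    expect_gte(fb, 0)
  }
  expect_error(focus_score(matrix(1, 2, 2)), "at least 3 x 3")
})

test_that("SSIM matches its defining identities", {
  set.seed(7)
  a <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim_score(a, a), 1, tolerance = 1e-6)

  # anti-correlated patches with (near-)zero local means score negative:
  # the luminance term stays ~1 while the structure term flips sign
  z <- 0.1 * outer(1:32, 1:32, function(i, j) (-1)^(i + j))
  expect_lt(ssim_score(z, -z), 0)

  # two independent noise fields are structurally dissimilar (near 0);
  # average over replicates to damp sampling noise
  s <- replicate(20, {
    x <- matrix(runif(32 * 32), 32, 32); y <- matrix(runif(32 * 32), 32, 32)
    ssim_score(x - mean(x), y - mean(y))
  })
  expect_lt(abs(mean(s)), 0.1)

  # symmetry
  b <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim_score(a, b), ssim_score(b, a))

  expect_error(ssim_score(a, b, window_px = 64), "window larger")
  expect_error(ssim_score(a, matrix(0, 8, 8)), "shapes differ")
})

test_that("a single nucleus yields one record assigned to its true layer", {
  p <- stack_params(n_layers = 14, width_px = 160, height_px = 160,
                    n_nuclei = 1, seed = 31)
  g <- generate_stack(p)
  masks <- segment_stack(g$stack, seg_config())
  dets <- detect_objects(g$stack, masks)
  expect_gt(length(dets), 1)  # visible in several focal planes
  rec <- link_and_assign(g$stack, masks, link_config())
  expect_equal(nrow(rec), 1)
  expect_equal(rec$assigned_layer, g$truth$layer[1])
  expect_equal(rec$depth_um, g$truth$layer[1] * 7)
  expect_equal(rec$n_member_layers, length(dets))
})

test_that("well-separated nuclei in one layer stay separate records", {
  p <- stack_params(n_layers = 3, width_px = 384, height_px = 384,
                    n_nuclei = 2, seed = 17,
                    depth_distribution = list(model = "surface", k = 10))
  g <- generate_stack(p)
  expect_equal(g$truth$layer, c(0L, 0L))  # both forced to the top layer
  masks <- segment_stack(g$stack, seg_config())
  rec <- link_and_assign(g$stack, masks, link_config())
  expect_equal(nrow(rec), 2)
  expect_equal(rec$assigned_layer, c(0L, 0L))
})

test_that("every detection lands in exactly one record (partition invariant)", {
  for (s in c(2, 5, 19)) {
    g <- generate_stack(small_params(seed = s, n_nuclei = 10))
    masks <- segment_stack(g$stack, seg_config())
    dets <- detect_objects(g$stack, masks)
    rec <- link_and_assign(g$stack, masks, link_config())
    members <- do.call(rbind, attr(rec, "members"))
    expect_equal(nrow(members), length(dets))
    expect_false(anyDuplicated(members) > 0)
    # no double counting: total nuclei never exceeds raw detections
    expect_lte(nrow(rec), length(dets))
  }
})

test_that("a handful of nuclei is recovered from many more raw detections", {
  # a six-layer scan in which five physical nuclei surface as >5 detections
  p <- stack_params(n_layers = 6, width_px = 448, height_px = 448,
                    n_nuclei = 5, seed = 12,
                    depth_distribution = list(model = "hill", n = 2, K = 20))
  g <- generate_stack(p)
  masks <- segment_stack(g$stack, seg_config())
  dets <- detect_objects(g$stack, masks)
  rec <- link_and_assign(g$stack, masks, link_config())
  expect_gt(length(dets), 5)
  expect_equal(nrow(rec), 5)
  ev <- evaluate_against_truth(rec, g$truth, 6)
  expect_equal(ev$n_duplicated_truth, 0)
})

test_that("greedy chaining matches the exhaustive oracle on mini-stacks", {
  for (s in 1:6) {
    p <- stack_params(n_layers = 3, width_px = 320, height_px = 320,
                      n_nuclei = 1 + s %% 3, seed = 100 + s)
    g <- generate_stack(p)
    masks <- segment_stack(g$stack, seg_config())
    lc <- link_candidates(g$stack, masks, link_config())
    rec <- link_and_assign(g$stack, masks, link_config())
    expect_identical(records_chains(rec),
                     oracle_best_grouping(lc$detections, lc$edges))
  }
})

test_that("count profiles tally records per layer", {
  rec <- structure(data.frame(nucleus_id = 1:3, assigned_layer = c(0L, 0L, 3L),
                              depth_um = c(0, 0, 21), x_px = 1:3, y_px = 1:3,
                              area_px = c(10L, 10L, 10L), axis_ratio = 1,
                              focus = 1, n_member_layers = 1L),
                   class = c("nucleus_records", "data.frame"))
  pr <- build_count_profile(rec, 4)
  expect_equal(pr$counts, c(2L, 0L, 0L, 1L))
  expect_equal(pr$C_summ, 3L)
  expect_error(build_count_profile(rec, 3), "out of range")

  empty <- rec[0, ]
  pr0 <- build_count_profile(empty, 4)
  expect_equal(pr0$counts, rep(0L, 4))
  expect_equal(pr0$C_summ, 0L)
})

test_that("link configuration is validated", {
  expect_error(link_config(ssim_window_px = 8), "odd")
  expect_error(link_config(max_centroid_shift_px = 0), "> 0")
  expect_error(link_config(ssim_threshold = 1.5), "\\[-1, 1\\]")
})
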