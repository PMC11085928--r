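test_that("tiling covers the image and reassembles exactly", {
  img <- matrix(runif(2048 * 2048 / 16), 512, 512)  # 512^2 stands in for 2048^2
  tl <- tile_image(img, 256, 0)
  expect_length(tl, 4)
  offsets <- t(vapply(tl, `[[`, c(x = 0, y = 0), "offset"))
  expect_setequal(paste(offsets[, 1], offsets[, 2]),
                  c("0 0", "0 256", "256 0", "256 256"))

  # non-divisible frame: single padded tile, stitched back to original size
  img2 <- matrix(runif(200 * 200), 200, 200)
  tl2 <- tile_image(img2, 256, 0)
  expect_length(tl2, 1)
  expect_equal(dim(tl2[[1]]$tile), c(256, 256))
  expect_equal(stitch_tiles(tl2, dim(img2)), img2)

  # overlapping tiles still round-trip
  tl3 <- tile_image(img2, 128, 32)
  expect_equal(stitch_tiles(tl3, dim(img2)), img2)

  expect_error(tile_image(img2, 64, 64), "exceed")
})

test_that("classical segmentation recovers well-separated nuclei", {
  p <- stack_params(n_layers = 2, width_px = 256, height_px = 256,
                    pixel_size_um = 1, n_nuclei = 3, seed = 8)
  pr <- generate_training_pairs(p, 1)
  cfg <- seg_config(min_area_px = 30)
  m <- segment_layer(pr[[1]]$image, cfg, layer_index = 0L)
  expect_s3_class(m, "layer_mask")
  expect_equal(m$n_objects, 3)
  expect_equal(sort(unique(as.vector(m$labels))), 0:3)

  # same input, same config: deterministic
  m2 <- segment_layer(pr[[1]]$image, cfg, layer_index = 0L)
  expect_identical(m$labels, m2$labels)
})

test_that("noise-only layers yield no objects once the area filter applies", {
  # with a calibrated threshold, 2% noise never clears it
  set.seed(1)
  noise <- matrix(pmax(rnorm(256 * 256, 0, 0.02), 0), 256, 256)
  m <- segment_layer(noise, seg_config(intensity_threshold = 0.25,
                                       min_area_px = 30))
  expect_equal(m$n_objects, 0)
  # fully blank layer is fine too
  m0 <- segment_layer(matrix(0, 64, 64), seg_config())
  expect_equal(m0$n_objects, 0)

  # within a stack, the pooled threshold keeps noise-only deep layers empty
  p <- stack_params(n_layers = 6, width_px = 256, height_px = 256,
                    n_nuclei = 4, seed = 3,
                    depth_distribution = list(model = "surface", k = 10))
  g <- generate_stack(p)
  masks <- segment_stack(g$stack, seg_config())
  expect_equal(vapply(masks[5:6], `[[`, 0L, "n_objects"), c(0L, 0L))
})

test_that("watershed splits touching nuclei and can be disabled", {
  img <- matrix(0, 200, 120)
  img <- pmax(img, 0.9 * ellipse_mask(200, 120, 70, 60, 26, 18))
  img <- pmax(img, 0.9 * ellipse_mask(200, 120, 115, 60, 26, 18))
  on <- segment_layer(img, seg_config(watershed_split = TRUE, min_area_px = 50))
  off <- segment_layer(img, seg_config(watershed_split = FALSE, min_area_px = 50))
  expect_equal(on$n_objects, 2)
  expect_equal(off$n_objects, 1)
})

test_that("area filter drops objects outside its bounds", {
  img <- matrix(0, 128, 128)
  img <- pmax(img, ellipse_mask(128, 128, 30, 30, 3, 3))    # ~28 px
  img <- pmax(img, ellipse_mask(128, 128, 90, 90, 15, 12))  # ~565 px
  m <- segment_layer(img, seg_config(min_area_px = 50, max_area_px = 1000,
                                     intensity_threshold = 0.5))
  expect_equal(m$n_objects, 1)
  m2 <- segment_layer(img, seg_config(min_area_px = 5, max_area_px = 100,
                                      intensity_threshold = 0.5))
  expect_equal(m2$n_objects, 1)
})

test_that("tiled segmentation matches whole-image segmentation away from borders", {
  p <- stack_params(n_layers = 2, width_px = 300, height_px = 300,
                    pixel_size_um = 1, n_nuclei = 6, seed = 13)
  pr <- generate_training_pairs(p, 1)
  cfg <- seg_config(min_area_px = 30, tile_size_px = 128, tile_overlap_px = 48)
  whole <- segment_layer(pr[[1]]$image, cfg)
  tiled <- segment_layer_tiled(pr[[1]]$image, cfg)
  expect_equal(tiled$n_objects, whole$n_objects)
  # object-by-object: every whole-image object has an identical tiled object
  for (i in seq_len(whole$n_objects)) {
    sel <- whole$labels == i
    j <- unique(tiled$labels[sel])
    expect_length(j, 1)
    expect_true(j > 0)
    expect_equal(sum(tiled$labels == j), sum(sel))
  }
})

test_that("overlap metrics satisfy their identities", {
  a <- matrix(0L, 8, 8); a[3:4, 3:4] <- 1L          # 2x2 block
  b <- matrix(0L, 8, 8); b[3, 3:4] <- 1L            # 1x2 half of it
  m <- overlap_metrics(a, b)
  expect_identical(m$iou, 0.5)
  expect_identical(m$dice, 2 / 3)
  expect_equal(m$dice_loss, 1 / 3)

  expect_equal(overlap_metrics(a, a), list(iou = 1, dice = 1, dice_loss = 0))
  disj <- matrix(0L, 8, 8); disj[7:8, 7:8] <- 1L
  expect_equal(overlap_metrics(a, disj)$iou, 0)
  expect_equal(overlap_metrics(a, disj)$dice, 0)

  # empty vs empty is defined as perfect agreement
  e <- matrix(0L, 4, 4)
  expect_equal(overlap_metrics(e, e), list(iou = 1, dice = 1, dice_loss = 0))

  expect_error(overlap_metrics(a, matrix(0L, 4, 4)), "shapes differ")
})

test_that("iou <= dice and both are symmetric, over random masks", {
  set.seed(42)
  for (i in 1:25) {
    a <- matrix(rbinom(400, 1, runif(1, 0.05, 0.6)), 20, 20)
    b <- matrix(rbinom(400, 1, runif(1, 0.05, 0.6)), 20, 20)
    ab <- overlap_metrics(a, b); ba <- overlap_metrics(b, a)
    expect_identical(ab, ba)
    expect_lte(ab$iou, ab$dice)
    expect_gte(ab$iou, 0); expect_lte(ab$dice, 1)
  }
})
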