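# Background subtraction, thresholding/labeling, and moment-based shape
# descriptors, checked against brute-force oracles.

test_that("background subtraction removes flat background, keeps small objects", {
  p <- segmentation_params(background_radius_px = 20)

  expect_true(all(preprocess_image(matrix(0.37, 64, 64), p) == 0))

  # a bright disc much smaller than the structuring element survives with
  # its integrated intensity almost intact (opening oracle removes it all)
  img <- matrix(0, 96, 96)
  rr <- row(img); cc <- col(img)
  img[(rr - 48)^2 + (cc - 48)^2 <= 36] <- 1
  out <- preprocess_image(img, p)
  expect_gt(sum(out), 0.99 * sum(img))
  open <- oracle_opening(img, 20)
  expect_lt(sum(open), 0.01 * sum(img))
  expect_true(max(abs(out - (img - open))) < 1e-6)

  # output is clamped non-negative for arbitrary input
  set.seed(1)
  noisy <- matrix(stats::runif(64^2), 64, 64)
  expect_gte(min(preprocess_image(noisy, p)), 0)

  expect_error(preprocess_image(array(0, c(4, 4, 2)), p), "2D")
})

test_that("segmentation labels objects, honors connectivity and area filter", {
  g <- gen_morphology_image(morphology_spec(n_blobs = 20, psf_sigma_px = 0,
                                            noise = list(gaussian_sd = 0,
                                                         poisson_scale = 0),
                                            seed = 11))
  lab <- segment_image(g$image, segmentation_params(threshold_method = "fixed",
                                                    fixed_threshold = 0.4))
  expect_equal(max(lab), 20L)

  # two squares touching only at one corner
  m <- matrix(0, 20, 20)
  m[3:8, 3:8] <- 1; m[9:14, 9:14] <- 1
  p4 <- segmentation_params(threshold_method = "fixed", fixed_threshold = 0.5,
                            connectivity = 4)
  p8 <- segmentation_params(threshold_method = "fixed", fixed_threshold = 0.5,
                            connectivity = 8)
  expect_equal(max(segment_image(m, p4)), 2L)
  expect_equal(max(segment_image(m, p8)), 1L)

  # an object one pixel below the minimum area is dropped
  m2 <- matrix(0, 16, 16)
  m2[2, 2:4] <- 1          # 3 px < min_object_area_px = 4
  m2[10:12, 10:12] <- 1    # 9 px
  lab2 <- segment_image(m2, segmentation_params(threshold_method = "fixed",
                                                fixed_threshold = 0.5))
  expect_equal(max(lab2), 1L)
  expect_equal(sum(lab2 > 0), 9L)

  # all-background input gives an empty map, not an error
  expect_equal(max(segment_image(matrix(0, 8, 8),
                                 segmentation_params(threshold_method = "fixed",
                                                     fixed_threshold = 0.5))), 0L)

  # the label map partitions the foreground
  expect_equal(sort(unique(as.integer(lab))), 0:20)
})

test_that("aspect ratio equals the second-moment oracle on known shapes", {
  # filled circle
  m <- matrix(0, 64, 64)
  m[(row(m) - 32)^2 + (col(m) - 32)^2 <= 200] <- 1
  d <- shape_descriptors(label_components(m, 8))
  expect_equal(d$aspect_ratio, 1, tolerance = 0.05)

  # axis-aligned 40 x 10 rectangle: moment axis ratio equals the side ratio
  r0 <- render_rect(40, 10, 0)
  d0 <- shape_descriptors(label_components(r0, 8))
  expect_equal(d0$aspect_ratio, 4, tolerance = 0.05)
  expect_equal(d0$aspect_ratio, oracle_moment_ar(r0), tolerance = 0.01)

  # the same rectangle rotated 30 degrees keeps its aspect ratio
  r30 <- render_rect(40, 10, 30)
  d30 <- shape_descriptors(label_components(r30, 8))
  expect_equal(d30$aspect_ratio, d0$aspect_ratio, tolerance = 0.02)
  expect_equal(d30$aspect_ratio, oracle_moment_ar(r30), tolerance = 0.01)

  # calibration adds physical areas
  dc <- shape_descriptors(label_components(r0, 8), um_per_px = 0.1)
  expect_equal(dc$area_um2, dc$area_px * 0.01)
})

test_that("aspect ratio is rotation invariant for objects above 200 px", {
  base <- shape_descriptors(label_components(render_rect(60, 12, 0), 8))$aspect_ratio
  for (th in seq(10, 170, by = 20)) {
    ar <- shape_descriptors(label_components(render_rect(60, 12, th), 8))$aspect_ratio
    expect_equal(ar, base, tolerance = 0.02)
  }
})

test_that("segmentation recovers generator truth on noise-free fixtures", {
  for (seed in 1:3) {
    g <- gen_morphology_image(morphology_spec(n_tubules = 8, n_blobs = 8,
                                              psf_sigma_px = 0,
                                              noise = list(gaussian_sd = 0,
                                                           poisson_scale = 0),
                                              seed = seed))
    seg <- segment_cell(g$image, segmentation_params(threshold_method = "fixed",
                                                     fixed_threshold = 0.4))
    expect_equal(max(seg$labels), nrow(g$objects))
    # match by centroid, compare AR to the moment oracle within 5%
    for (i in seq_len(nrow(seg$objects))) {
      j <- which.min((g$objects$centroid_row - seg$objects$centroid_row[i])^2 +
                       (g$objects$centroid_col - seg$objects$centroid_col[i])^2)
      expect_equal(seg$objects$aspect_ratio[i], g$objects$true_ar[j],
                   tolerance = 0.05)
    }
  }
})
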