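# The generators must be deterministic, internally consistent with their
# ground-truth tables, and must render what their spec promises.

test_that("all four generators are bit-identical under identical spec + seed", {
  m1 <- gen_morphology_image(morphology_spec(n_tubules = 5, n_blobs = 5, seed = 42))
  m2 <- gen_morphology_image(morphology_spec(n_tubules = 5, n_blobs = 5, seed = 42))
  expect_identical(m1$image, m2$image)
  expect_identical(m1$objects, m2$objects)
  m3 <- gen_morphology_image(morphology_spec(n_tubules = 5, n_blobs = 5, seed = 43))
  expect_false(identical(m1$image, m3$image))

  t1 <- gen_timelapse(timelapse_spec(n_frames = 30, n_events = 2, seed = 7))
  t2 <- gen_timelapse(timelapse_spec(n_frames = 30, n_events = 2, seed = 7))
  expect_identical(t1$foci, t2$foci)
  expect_identical(t1$truth, t2$truth)

  e1 <- gen_em_scene(em_scene_spec(seed = 9))
  e2 <- gen_em_scene(em_scene_spec(seed = 9))
  expect_identical(e1$scene, e2$scene)

  p1 <- gen_pagfp_series(pagfp_spec(seed = 5))
  p2 <- gen_pagfp_series(pagfp_spec(seed = 5))
  expect_identical(p1$frames, p2$frames)
})

test_that("morphology ground truth matches its rendered mask", {
  # circles have unit axis ratio and imply a fragmented network
  g <- gen_morphology_image(morphology_spec(n_blobs = 20, psf_sigma_px = 0,
                                            noise = list(gaussian_sd = 0,
                                                         poisson_scale = 0),
                                            seed = 1))
  expect_equal(g$class, "Fragmented")
  expect_true(all(abs(g$objects$true_ar - 1) <= 0.05))

  # tubules imply an elongated network; per-object truth agrees with an
  # independent pixel-moment oracle on each object's own mask
  g2 <- gen_morphology_image(morphology_spec(n_tubules = 12, seed = 2))
  expect_equal(g2$class, "Elongated")
  for (id in g2$objects$object_id) {
    expect_equal(g2$objects$true_ar[id],
                 oracle_moment_ar(g2$labels == id), tolerance = 1e-6)
  }
  expect_true(all(g2$objects$true_ar > 2))

  # objects stay away from the image border
  border <- c(g2$mask[1, ], g2$mask[nrow(g2$mask), ],
              g2$mask[, 1], g2$mask[, ncol(g2$mask)])
  expect_true(all(border == 0))

  # an impossible packing is a placement error, not an infinite loop
  expect_error(gen_morphology_image(
    morphology_spec(n_blobs = 500, image_size_px = c(64, 64), seed = 1)),
    "place")
})

test_that("time-lapse events are rendered for the programmed spans", {
  # dwell 18 s at 3 s/frame: the focus is present on 7 consecutive frames
  tl <- gen_timelapse(timelapse_spec(n_frames = 30, n_events = 1,
                                     dwell_dist = list(name = "point", value = 18),
                                     max_start_frame = 3, seed = 3))
  present <- vapply(tl$foci, function(fr) max(fr) > 0.5, logical(1))
  expect_equal(sum(present), 7L)
  expect_true(all(which(present) == seq(tl$truth$start_frame, tl$truth$end_frame)))
  expect_equal(tl$truth$duration_s, 18)

  # p_fusion = 1: every outcome fused and each event merges one pair
  tf <- gen_timelapse(timelapse_spec(n_frames = 40, n_events = 4, p_fusion = 1,
                                     dwell_dist = list(name = "point", value = 30),
                                     seed = 4))
  expect_true(all(tf$truth$outcome == "fused"))
  n_first <- max(label_components(tf$mito[[1]] > 0.3, 8))
  n_last <- max(label_components(tf$mito[[40]] > 0.3, 8))
  expect_equal(n_first, 8L)   # 4 pairs
  expect_equal(n_last, 4L)    # each pair merged

  # point-mass dwell: mean true duration is exact
  tp <- gen_timelapse(timelapse_spec(n_frames = 60, n_events = 20,
                                     dwell_dist = list(name = "point", value = 30),
                                     seed = 5))
  expect_equal(mean(tp$truth$duration_s), 30)

  # durations that cannot fit are a generation error
  expect_error(timelapse_spec(n_frames = 10,
                              dwell_dist = list(name = "point", value = 300)),
               "fit")
})

test_that("EM scenes honor the 60 nm contact rule in their truth tables", {
  em <- gen_em_scene(em_scene_spec(
    n_mito = 1,
    er_segments = data.frame(target = 1, standoff_nm = 100, arc_length_nm = 300),
    seed = 1))
  expect_equal(nrow(em$truth_contacts), 0L)
  expect_equal(sum(em$scene$object_type == "er") > 0, TRUE)

  em2 <- gen_em_scene(em_scene_spec(
    n_mito = 1,
    er_segments = data.frame(target = c(1, 1), standoff_nm = c(10, 40),
                             arc_length_nm = c(200, 200)),
    seed = 2))
  expect_equal(nrow(em2$truth_contacts), 2L)
  expect_equal(sort(em2$truth_contacts$gap_bin), c("[0,15)", "[30,60]"))
  expect_equal(em2$truth_contacts$length_nm, c(200, 200))
  expect_equal(em2$truth_contacts$gap_nm, c(10, 40))
})

test_that("PA-GFP truth curves are ratios of spread fractions", {
  p <- gen_pagfp_series(pagfp_spec(spread_fractions = c(0.2, 0.2, 0.2)))
  expect_equal(p$truth$true_normalized_area, c(1, 1, 1))

  p2 <- gen_pagfp_series(pagfp_spec(spread_fractions = c(0.2, 0.6, 1.0)))
  expect_equal(p2$truth$true_normalized_area, c(1, 3, 5))

  # activation is contained in its component
  expect_true(max(p2$truth$true_normalized_area) <= 1 / 0.2 + 1e-9)

  expect_error(pagfp_spec(activated_component = 9), "out of range")
  expect_error(pagfp_spec(spread_fractions = c(0.2, 0.5, 0.4)), "non-decreasing")
  expect_error(pagfp_spec(roi_fraction = 0.3,
                          spread_fractions = c(0.2, 0.5, 0.9)), "equal")
})
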