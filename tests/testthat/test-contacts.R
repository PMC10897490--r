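# Contact-site geometry: distance sampling against polygon surfaces, run
# extraction at the 60 nm rule, GAP binning, and perimeter coverage.

square_poly <- function(side = 400, x0 = 0, y0 = 0) {
  cbind(x = x0 + c(0, side, side, 0), y = y0 + c(0, 0, side, side))
}

circle_poly <- function(r, n = 256, x0 = 0, y0 = 0) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = x0 + r * cos(a), y = y0 + r * sin(a))
}

test_that("sampled distances match plane geometry and the nearest surface", {
  # straight ER parallel to a square's top edge at offset 30 nm
  er <- cbind(x = seq(50, 350, length.out = 61), y = 430)
  s <- sample_distances(er, list(square_poly()), step_nm = 5)
  expect_true(all(abs(s$dist_nm - 30) < 1e-6))

  # a vertex on the boundary has distance zero
  er0 <- cbind(x = c(100, 200), y = c(400, 400))
  s0 <- sample_distances(er0, list(square_poly()), step_nm = 5)
  expect_true(all(s0$dist_nm < 1e-9))

  # equidistant between two mitochondria, nudged toward the second
  m1 <- circle_poly(100, x0 = 0); m2 <- circle_poly(100, x0 = 500)
  er2 <- cbind(x = c(251, 251), y = c(-20, 20))
  s2 <- sample_distances(er2, list(m1, m2), step_nm = 5)
  expect_true(all(s2$mito_id == 2))
  # distances agree with a dense boundary-sampling oracle
  for (i in seq_len(nrow(s2))) {
    p <- c(er2[1, 1], seq(-20, 20, by = 5)[i])
    expect_equal(s2$dist_nm[i],
                 min(oracle_poly_dist(p, m1), oracle_poly_dist(p, m2)),
                 tolerance = 1e-3)
  }

  expect_error(sample_distances(er2[1, , drop = FALSE], list(m1)), ">= 2")
})

test_that("contact runs follow the 60 nm rule", {
  # uniform 20 nm over a 200 nm trace: one contact, bin [15,30)
  er <- cbind(x = seq(100, 300, length.out = 41), y = 420)
  s <- sample_distances(er, list(square_poly()), step_nm = 5)
  cc <- extract_contacts(s)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$length_nm, 200, tolerance = 1e-6)
  expect_equal(cc$gap_nm, 20, tolerance = 1e-6)
  expect_equal(cc$gap_bin, "[15,30)")

  # wholly beyond 60 nm: no contacts
  er_far <- cbind(x = seq(100, 300, length.out = 41), y = 500)
  s_far <- sample_distances(er_far, list(square_poly()), step_nm = 5)
  expect_equal(nrow(extract_contacts(s_far)), 0L)

  # dipping under 60 nm twice -> 2 contacts, matching the run oracle
  y <- 400 + c(rep(30, 10), rep(80, 6), rep(50, 10))
  er2 <- cbind(x = seq(100, 100 + 5 * (length(y) - 1), by = 5), y = y)
  s2 <- sample_distances(er2, list(square_poly()), step_nm = 5)
  cc2 <- extract_contacts(s2)
  runs <- oracle_runs(s2$dist_nm, s2$mito_id)
  expect_equal(nrow(cc2), 2L)
  expect_equal(length(runs), 2L)
  for (k in seq_along(runs)) {
    expect_equal(cc2$n_samples[k], runs[[k]][2] - runs[[k]][1] + 1)
  }
})

test_that("GAP bins partition contacts with the stated boundaries", {
  cc <- data.frame(gap_nm = c(5, 20, 45),
                   gap_bin = c("[0,15)", "[15,30)", "[30,60]"))
  expect_equal(unname(bin_gaps(cc)), c(1L, 1L, 1L))

  # 15 falls in the middle bin (half-open-left convention)
  c15 <- data.frame(gap_nm = 15, gap_bin = mitoquant:::.gap_bin_label(15))
  expect_equal(unname(bin_gaps(c15)), c(0L, 1L, 0L))
  expect_equal(mitoquant:::.gap_bin_label(60), "[30,60]")

  expect_equal(sum(bin_gaps(cc[0, ])), 0L)
  expect_error(bin_gaps(data.frame(gap_nm = 70, gap_bin = "[30,60]")), "60")
})

test_that("coverage uses the union of projected arcs", {
  # a 200 nm contact on a 1000 nm-perimeter circle covers 20%
  r <- 1000 / (2 * pi)
  em <- gen_em_scene(em_scene_spec(
    n_mito = 1, mito_radius_nm = r,
    er_segments = data.frame(target = 1, standoff_nm = 5, arc_length_nm = 200 * (r + 5) / r),
    seed = 1))
  res <- analyze_contacts(as_scene(em$scene))
  expect_equal(res$summary$percent_perimeter_covered, 20, tolerance = 0.5)

  # two ER traces over the same sector count once, not twice
  m <- list(circle_poly(200))
  a <- seq(0, pi / 2, length.out = 60)
  er_in <- cbind(x = 220 * cos(a), y = 220 * sin(a))
  er_out <- cbind(x = 240 * cos(a), y = 240 * sin(a))
  scene <- structure(list(mito = m, er = list(er_in, er_out), cell_id = 1),
                     class = "annotated_scene")
  res2 <- analyze_contacts(scene)
  expect_equal(nrow(res2$contacts), 2L)
  expect_equal(res2$summary$percent_perimeter_covered, 25, tolerance = 1)

  # contacts per mitochondrion is a plain ratio
  em3 <- gen_em_scene(em_scene_spec(
    n_mito = 2,
    er_segments = data.frame(target = c(1, 1, 2), standoff_nm = c(10, 30, 50),
                             arc_length_nm = c(200, 200, 200)),
    seed = 3))
  res3 <- analyze_contacts(as_scene(em3$scene))
  expect_equal(res3$summary$contacts_per_mito, 1.5)
  # total contact length cannot exceed total ER length
  er_len <- sum(vapply(as_scene(em3$scene)$er, function(p) {
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1)))
  expect_lte(sum(res3$contacts$length_nm), er_len + 3 * 5)
})

test_that("halving the sampling step changes lengths and coverage < 1%", {
  em <- gen_em_scene(em_scene_spec(
    n_mito = 2,
    er_segments = data.frame(target = c(1, 2), standoff_nm = c(12, 48),
                             arc_length_nm = c(350, 250)),
    seed = 4))
  scene <- as_scene(em$scene)
  r5 <- analyze_contacts(scene, step_nm = 5)
  r25 <- analyze_contacts(scene, step_nm = 2.5)
  expect_equal(r5$summary$percent_perimeter_covered,
               r25$summary$percent_perimeter_covered, tolerance = 0.01)
  expect_equal(sum(r5$contacts$length_nm), sum(r25$contacts$length_nm),
               tolerance = 0.01)
})

test_that("scene round-trips through the annotation CSV layout", {
  em <- gen_em_scene(em_scene_spec(nm_per_unit = 2, seed = 5))
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(em$scene, tf, row.names = FALSE)
  scene <- read_scene_csv(tf, nm_per_unit = 2)
  res <- analyze_contacts(scene)
  expect_equal(nrow(res$contacts), nrow(em$truth_contacts))
  expect_equal(sort(res$contacts$gap_nm), sort(em$truth_contacts$gap_nm),
               tolerance = 0.01)
  expect_error(read_scene_csv(tempfile()), "not found")
})
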