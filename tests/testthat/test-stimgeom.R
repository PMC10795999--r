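# Trajectory geometry, projection, alignment, rendering and schedules.

test_that("angular diameter follows the pinhole relation and its monotonicities", {
  expect_equal(round(angular_diameter(0.06, 2.75), 2), 1.25)
  expect_equal(round(angular_diameter(0.084, 2.75), 2), 1.75)
  expect_lt(angular_diameter(0.06, 1e6), 1e-4)
  ## strictly decreasing in distance, increasing in sphere size
  d <- seq(0.5, 12, length.out = 40)
  expect_true(all(diff(angular_diameter(0.06, d)) < 0))
  s <- seq(0.01, 0.2, length.out = 40)
  expect_true(all(diff(angular_diameter(s, 2)) > 0))
  expect_error(angular_diameter(0, 1), "sphere_diameter")
  expect_error(angular_diameter(0.06, 0), "distance")
})

test_that("time to collision is distance over speed in rounded ms", {
  expect_identical(time_to_collision(3.3, 24), 138)
  expect_identical(time_to_collision(2.75, 24), 115)
  expect_identical(time_to_collision(0, 24), 0)
  expect_error(time_to_collision(1, 0), "speed")
  expect_error(time_to_collision(-1, 24), "distance")
})

test_that("projection matches direct trigonometry and is sign-correct", {
  sp <- trajectory_spec(11.3, 3.3, 24, start_lateral_offset = 0.65,
                        start_vertical_offset = 0.38,
                        impact_lateral_offset = 0.65, quadrant = "UR")
  pp <- project_trajectory(sp, n_frames = 10)
  expect_equal(pp$angular_x[1], atan(0.65 / 11.3) * 180 / pi,
               tolerance = 1e-10)
  expect_gt(pp$angular_y[1], 0)   # upper quadrant -> +y

  ## axial motion: all offsets zero -> on the gaze axis at every frame
  ax <- project_trajectory(trajectory_spec(10, 1, 24), n_frames = 20)
  expect_true(all(ax$angular_x == 0) && all(ax$angular_y == 0))

  ## approach -> strictly increasing angular size
  expect_true(all(diff(ax$angular_size) > 0))

  ## left quadrants are mirrored in sign
  lf <- project_trajectory(trajectory_spec(10, 1, 24, 0.5, 0.3,
                                           quadrant = "LL"), n_frames = 5)
  expect_true(all(lf$angular_x < 0) && all(lf$angular_y < 0))

  expect_error(project_trajectory(trajectory_spec(3, 0, 24), n_frames = 5),
               NA)  # reaching 0 exactly at the final frame is allowed
})

test_that("time-to-collision is conserved along a constant-speed approach", {
  sp <- trajectory_spec(11.3, 3.3, 24)
  pp <- project_trajectory(sp, n_frames = 21)
  ttc0 <- 11.3 / 24
  z <- 11.3 - 24 * pp$frame_times
  expect_equal(z / 24, ttc0 - pp$frame_times, tolerance = 1e-12)
  ## travel 8 m at 24 m/s ~ 1/3 s -> 20 frames at 60 Hz
  expect_identical(length(project_trajectory(sp)$frame_times), 20L)
})

test_that("centroid alignment equalizes centroids, is symmetric and idempotent", {
  sp1 <- trajectory_spec(8.75, 0.75, 24, 0.65, 0.38, 0, quadrant = "UR")
  sp2 <- trajectory_spec(8.75, 0.75, 24, 0.65, 0.38, 0.06, quadrant = "UR")
  p1 <- project_trajectory(sp1)
  p2 <- project_trajectory(sp2)

  al <- align_by_centroid(list(p1, p2))
  cents <- vapply(al, loomsight:::path_centroid, numeric(2))
  expect_lt(max(abs(cents[, 1] - cents[, 2])), 1e-9)

  ## identical paths -> zero shifts
  same <- align_by_centroid(list(p1, p1))
  expect_equal(same[[1]]$centroid_shift, c(0, 0), tolerance = 1e-12)

  ## horizontally mirrored paths -> equal magnitude, opposite sign in x
  m1 <- p1; m1$angular_x <- -m1$angular_x; m1$quadrant <- p1$quadrant
  mir <- align_by_centroid(list(p1, m1))
  expect_equal(mir[[1]]$centroid_shift[1], -mir[[2]]$centroid_shift[1],
               tolerance = 1e-12)

  ## idempotent: realigning aligned paths shifts nothing further
  al2 <- align_by_centroid(al)
  extra <- vapply(seq_along(al), function(i)
    max(abs(al2[[i]]$centroid_shift - al[[i]]$centroid_shift)), numeric(1))
  expect_lt(max(extra), 1e-12)

  expect_error(align_by_centroid(list()), "empty")
})

test_that("rendered discs have the projected area and obey raster invariants", {
  sp <- trajectory_spec(8.75, 2, 24, 0.05, 0.05)
  pp <- project_trajectory(sp, n_frames = 6)
  fs <- render_frames(pp, resolution = 128, field_of_view = 8)
  expect_identical(dim(fs$frames), c(128L, 128L, 6L))
  expect_true(all(fs$frames >= 0 & fs$frames <= 1))

  ## disc pixel area grows as angular_size^2
  area <- vapply(seq_len(6), function(k)
    sum(fs$frames[, , k] > fs$background_level + 0.25), numeric(1))
  fit <- lm(log(area) ~ log(pp$angular_size))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.1)

  ## zero-size disc -> pure background; static path -> identical frames
  zp <- pp; zp$angular_size <- rep(0, 6)
  zf <- render_frames(zp, resolution = 64, field_of_view = 8)
  expect_true(all(zf$frames == zf$background_level))
  st <- pp
  st$angular_size <- rep(1, 6); st$angular_x <- rep(0.5, 6)
  st$angular_y <- rep(0.5, 6)
  sf <- render_frames(st, resolution = 64, field_of_view = 8)
  expect_true(all(sf$frames[, , 1] == sf$frames[, , 4]))

  ## disc beyond the field of view warns and clips
  big <- pp; big$angular_size <- rep(20, 6)
  expect_warning(render_frames(big, resolution = 64, field_of_view = 8),
                 "field of view")
})

test_that("trial schedules are balanced, seeded and ISI-constrained", {
  facs <- list(attention = c("att", "unatt"),
               trajectory = c("hit", "miss"),
               quadrant = c("UL", "UR", "LL", "LR"))
  ## 8 runs x 32 trials: attention blocked over runs in the real design;
  ## here the full crossing gives the same per-cell counts
  sch <- make_trial_schedule(facs, runs = 8, trials_per_run = 32,
                             isi_choices = c(8, 10, 12), seed = 11)
  counts <- table(sch$attention, sch$trajectory, sch$quadrant)
  expect_true(all(counts == 16))
  expect_true(all(sch$isi %in% c(8, 10, 12)))

  sch3 <- make_trial_schedule(list(trajectory = c("hit", "miss", "recede"),
                                   field = c("NVF", "BVF")),
                              runs = 1, trials_per_run = 24,
                              isi_choices = c(8, 10, 12, 14), seed = 2)
  expect_identical(nrow(sch3), 24L)
  expect_true(all(table(sch3$trajectory, sch3$field) == 4))

  one <- make_trial_schedule(list(a = 1:2, b = 1:2, c = 1:2), 1, 8,
                             isi_choices = 2, seed = 5)
  expect_true(all(table(one$a, one$b, one$c) == 1))

  expect_error(make_trial_schedule(facs, 1, 30, c(8, 10), seed = 1),
               "divisible")
  expect_identical(make_trial_schedule(facs, 2, 16, c(8, 10), seed = 7),
                   make_trial_schedule(facs, 2, 16, c(8, 10), seed = 7))
})

test_that("eccentric positions decompose into screen offsets", {
  comp <- eccentricity_components(3.8, 60)
  expect_equal(unname(comp["vertical"]), 1.90, tolerance = 1e-10)
  expect_equal(unname(comp["horizontal"]), 3.8 * sin(pi / 3),
               tolerance = 1e-10)
})

test_that("trajectory specs validate their geometry", {
  expect_error(trajectory_spec(3, 5, 24), "approach")
  expect_error(trajectory_spec(5, 3, -1), "speed")
  expect_silent(trajectory_spec(0.75, 8.75, 24, direction = "recede"))
  expect_error(trajectory_spec(5, 3, 24, sphere_diameter = 0), "sphere")
})
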