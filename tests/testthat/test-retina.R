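test_that("relative bearings follow the signed left-positive convention", {
  expect_equal(relative_bearing(0, 0, 0, 1, 0), 0)
  expect_equal(relative_bearing(0, 0, 0, 0, 1), 90)
  expect_equal(relative_bearing(0, 0, 90, 1, 0), -90)
  expect_error(relative_bearing(1, 2, 0, 1, 2), "coincides")

  # rotate-frame oracle: express the target in the focal frame with a 2-D
  # rotation matrix and read the bearing off atan2
  set.seed(11)
  for (i in 1:50) {
    p <- runif(2, -3, 3); q <- runif(2, -3, 3); h <- runif(1, -180, 180)
    if (all(p == q)) next
    th <- -h * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) # R(-h)
    loc <- rot %*% (q - p)
    expect_equal(relative_bearing(p[1], p[2], h, q[1], q[2]),
                 atan2(loc[2], loc[1]) * 180 / pi, tolerance = 1e-10)
  }
  expect_equal(wrap_angle(c(370, 539, -190)), c(10, 179, 170))
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
})

test_that("vertical occupancy is 2*atan(H/d) degrees and decreasing in d", {
  expect_equal(vertical_occupancy(0.15, 0.42), 39.30765, tolerance = 1e-5)
  expect_equal(vertical_occupancy(0.075, 0.92), 9.321091, tolerance = 1e-5)
  expect_equal(vertical_occupancy(0, 2.7), 0)
  d <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(vertical_occupancy(0.2, d)) < 0))
  expect_error(vertical_occupancy(0.1, 0), "distance")
  expect_error(vertical_occupancy(0.1, -1), "distance")

  # brute-force oracle: subtended angle of 1e5 points sampled on the
  # object's vertical extent
  for (case in list(c(0.15, 0.42), c(0.4, 1.3), c(0.75, 0.8))) {
    z <- seq(-case[1], case[1], length.out = 1e5)
    sub <- (max(atan(z / case[2])) - min(atan(z / case[2]))) * 180 / pi
    expect_lt(abs(vertical_occupancy(case[1], case[2]) - sub), 0.01)
  }
})

test_that("per-object occupancy profiles split eyes and respect the blind zone", {
  empty <- occupancy_profile(0, 0, 0, NULL)
  expect_equal(nrow(empty), 0)
  expect_equal(unname(total_occupancy(empty)), c(0, 0))

  # dead ahead: exactly one eye (right, by the stated tie-break)
  ahead <- occupancy_profile(0, 0, 0, visual_objects(1, 0, 0.2))
  expect_equal(nrow(ahead), 1)
  expect_equal(ahead$eye, "right")

  # object behind the fish (bearing 180) is in the blind zone
  behind <- occupancy_profile(0, 0, 0, visual_objects(-1, 0, 0.2))
  expect_equal(nrow(behind), 0)
  edge <- occupancy_profile(0, 0, 0,
                            visual_objects(cos(166 * pi / 180),
                                           sin(166 * pi / 180), 0.2))
  expect_equal(nrow(edge), 0)

  # eyes assigned by bearing sign
  two <- occupancy_profile(0, 0, 0, visual_objects(c(0, 0), c(1, -1),
                                                   c(0.2, 0.2)))
  expect_setequal(two$eye, c("left", "right"))
  expect_equal(two$eye[two$bearing_deg > 0], "left")
})

test_that("mirror symmetry across the heading axis swaps the eyes exactly", {
  set.seed(21)
  for (i in 1:20) {
    obj <- random_scene(5)
    prof <- occupancy_profile(0, 0, 0, obj)
    mirr <- occupancy_profile(0, 0, 0,
                              visual_objects(obj$x, -obj$y, obj$half_extent))
    prof <- prof[order(prof$object_id), ]
    mirr <- mirr[order(mirr$object_id), ]
    expect_equal(prof$occupancy_deg, mirr$occupancy_deg)
    expect_equal(prof$bearing_deg, -mirr$bearing_deg)
    on_axis <- abs(prof$bearing_deg) < 1e-12
    expect_equal(prof$eye[!on_axis],
                 ifelse(mirr$eye[!on_axis] == "left", "right", "left"))
  }
})

test_that("rasterized profiles give covered cells to the nearest object", {
  # two collinear objects at the same bearing: cells carry the nearer one
  obj <- visual_objects(c(1, 2), c(0.4, 0.8), c(0.2, 0.2))
  ras <- occupancy_profile(0, 0, 0, obj, mode = "rasterized")
  both <- ras$bearing_deg %in%
    intersect(ras$bearing_deg[ras$object_id == 1],
              ras$bearing_deg)
  near_cells <- ras[ras$object_id == 1, ]
  expect_true(all(near_cells$occupancy_deg ==
                    vertical_occupancy(0.2, sqrt(1 + 0.4^2))))
  # the far object only keeps cells the near one does not cover
  far_cells <- ras[ras$object_id == 2, ]
  expect_true(all(!(far_cells$bearing_deg %in% near_cells$bearing_deg)))

  # each eye has at most 165 one-degree cells, each counted once
  set.seed(31)
  for (i in 1:10) {
    ras <- occupancy_profile(0, 0, runif(1, -180, 180), random_scene(6),
                             mode = "rasterized")
    expect_true(all(table(ras$eye) <= 165))
    expect_false(any(duplicated(ras$bearing_deg)))
  }
})

test_that("rasterized occupancy matches 0.01-degree ray casting", {
  set.seed(41)
  for (i in 1:10) {
    h <- runif(1, -180, 180)
    obj <- random_scene(3)
    ras <- occupancy_profile(0, 0, h, obj, mode = "rasterized")
    got <- total_occupancy(ras)
    want <- raycast_totals(0, 0, h, obj)
    # agreement within one grid cell's worth of the largest occupancy
    tol <- max(vertical_occupancy(obj$half_extent,
                                  sqrt(obj$x^2 + obj$y^2)))
    expect_lt(abs(got[["left"]] - want[["left"]]), tol)
    expect_lt(abs(got[["right"]] - want[["right"]]), tol)
  }
})

test_that("looming input is the maximal per-object occupancy increase", {
  # static scene, static focal: zero in both modes
  obj <- random_scene(4)
  for (mode in c("neighbor_induced", "raw")) {
    li <- looming_from_scene(c(0, 0, 0), c(0, 0, 0), obj, obj, mode)
    expect_equal(li$value, 0)
  }

  # an approaching object: 1.0 -> 0.9 cm at half-extent 0.2
  now <- visual_objects(0.9, 0, 0.2)
  prev <- visual_objects(1.0, 0, 0.2)
  li <- looming_from_scene(c(0, 0, 0), c(0, 0, 0), now, prev)
  expect_equal(li$value, 2.4365, tolerance = 1e-3)
  expect_equal(li$object_id, 1)

  # max over objects: increases of about 1 and 3 degrees -> the larger
  now2 <- visual_objects(c(0, 0), c(2.262, -1.432), c(0.2, 0.2))
  prev2 <- visual_objects(c(0, 0), c(2.4, -1.6), c(0.2, 0.2))
  li2 <- looming_from_scene(c(0, 0, 0), c(0, 0, 0), now2, prev2)
  inc2 <- vertical_occupancy(0.2, 1.432) - vertical_occupancy(0.2, 1.6)
  expect_equal(li2$value, inc2, tolerance = 1e-6)
  expect_equal(li2$object_id, 2)

  # a newly appearing object counts with its full occupancy
  li3 <- looming_input(
    occupancy_profile(0, 0, 0, visual_objects(1.5, 0.2, 0.3)),
    occupancy_profile(0, 0, 0, NULL))
  expect_equal(li3$value, vertical_occupancy(0.3, sqrt(1.5^2 + 0.2^2)))
})

test_that("neighbor-induced looming ignores the focal fish's own motion", {
  set.seed(51)
  obj <- random_scene(6, d_range = c(1, 3))
  for (i in 1:30) {
    pose_prev <- c(runif(2, -0.5, 0.5), runif(1, -180, 180))
    pose_now <- pose_prev + c(runif(2, -0.1, 0.1), runif(1, -40, 40))
    li <- looming_from_scene(pose_now, pose_prev, obj, obj,
                             mode = "neighbor_induced")
    expect_equal(li$value, 0)
  }
})
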