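# Proximity, orientation, movement and contact features.

test_that("shoulder_center is the componentwise midpoint", {
  dy <- const_dyad(5)
  dy$parent$pos[, 3, ] <- matrix(c(0, 1, 0), 5, 3, byrow = TRUE)
  dy$parent$pos[, 4, ] <- matrix(c(0.4, 1, 0), 5, 3, byrow = TRUE)
  expect_equal(shoulder_center(dy, "parent")[1, ], c(0.2, 1, 0))
  dy$parent$pos[, 4, ] <- dy$parent$pos[, 3, ]       # coincident shoulders
  expect_equal(shoulder_center(dy, "parent")[1, ], c(0, 1, 0))
  dy$parent$pos[, 4, ] <- -dy$parent$pos[, 3, ]      # symmetric about origin
  expect_equal(shoulder_center(dy, "parent")[1, ], c(0, 0, 0))
})

test_that("distance_to_table matches hand computation and is rigid-invariant", {
  clock <- make_clock(0, 0.1, 30)
  track <- matrix(rep(c(0.6, 0.6, 0.6), each = 4), 4, 3)
  d <- distance_to_table(track, clock)
  expect_equal(d$values[1], sqrt(1.08), tolerance = 1e-12)
  expect_equal(distance_to_table(matrix(0, 4, 3), clock)$values, rep(0, 4))
  # translating table and points together leaves distances unchanged
  shift <- c(1, -2, 3)
  d2 <- distance_to_table(sweep(track, 2, -shift), clock, table_center = shift)
  expect_equal(d2$values, d$values)
})

test_that("all distance features are invariant under a world rigid motion", {
  set.seed(41)
  dy <- const_dyad(20)
  dy$parent$pos <- dy$parent$pos + array(stats::rnorm(600, 0, 0.02), c(20, 10, 3))
  dy$child$pos <- dy$child$pos + array(stats::rnorm(600, 0, 0.02), c(20, 10, 3))
  R <- random_rotation(); tv <- stats::rnorm(3)
  Tm <- rigid_transform(R, tv)
  dy2 <- dy
  for (role in c("parent", "child")) {
    flat <- apply_transform(Tm, matrix(dy[[role]]$pos, ncol = 3))
    dy2[[role]]$pos <- array(flat, c(20, 10, 3))
  }
  h1 <- hand_distances(dy); h2 <- hand_distances(dy2)
  expect_equal(h2[[1]]$values, h1[[1]]$values, tolerance = 1e-9)
  expect_equal(h2[[2]]$values, h1[[2]]$values, tolerance = 1e-9)
  tc2 <- as.numeric(apply_transform(Tm, c(0, 0, 0)))
  d1 <- distance_to_table(shoulder_center(dy, "parent"), dy$clock)
  d2 <- distance_to_table(shoulder_center(dy2, "parent"), dy$clock,
                          table_center = tc2)
  expect_equal(d2$values, d1$values, tolerance = 1e-9)
})

test_that("closest_hand_to_table takes the min and tolerates one-hand gaps", {
  dy <- const_dyad(6)
  dy$parent$pos[, 9, ] <- matrix(c(0.2, 0, 0), 6, 3, byrow = TRUE)  # hand_left
  dy$parent$pos[, 10, ] <- matrix(c(0.5, 0, 0), 6, 3, byrow = TRUE) # hand_right
  f <- closest_hand_to_table(dy, "parent")
  expect_equal(f$values, rep(0.2, 6))
  dy$parent$pos[3, 9, ] <- NA; dy$parent$gap[3, 9] <- TRUE
  f2 <- closest_hand_to_table(dy, "parent")
  expect_equal(f2$values[3], 0.5)
  dy$parent$pos[4, 10, ] <- NA; dy$parent$gap[4, 10] <- TRUE
  dy$parent$pos[4, 9, ] <- NA; dy$parent$gap[4, 9] <- TRUE
  f3 <- closest_hand_to_table(dy, "parent")
  expect_true(f3$gap[4])
})

test_that("shoulder orientation hits the 0/45/90 reference geometry", {
  expect_equal(shoulder_orientation(orient_pair(c(0, 0, 1)), "parent")$values,
               rep(0, 3))
  expect_equal(shoulder_orientation(orient_pair(c(1, 0, 0)), "parent")$values,
               rep(90, 3))
  # torso in either seat facing the table center: line (-+sqrt2/2, 0, sqrt2/2)
  sq <- sqrt(2) / 2
  expect_equal(shoulder_orientation(orient_pair(c(-sq, 0, sq)), "parent")$values,
               rep(45, 3), tolerance = 1e-9)
  expect_equal(shoulder_orientation(orient_pair(c(sq, 0, sq)), "parent")$values,
               rep(45, 3), tolerance = 1e-9)
})

test_that("relative orientation: face-to-face 0, orthogonal 90", {
  expect_equal(relative_shoulder_orientation(
    orient_pair(c(1, 0, 0), c(1, 0, 0)))$values, rep(0, 3))
  expect_equal(relative_shoulder_orientation(
    orient_pair(c(1, 0, 0), c(0, 0, 1)))$values, rep(90, 3))
  sq <- sqrt(2) / 2
  expect_equal(relative_shoulder_orientation(
    orient_pair(c(-sq, 0, sq), c(sq, 0, sq)))$values, rep(90, 3),
    tolerance = 1e-9)
})

test_that("orientations live in [0, 90] and ignore shoulder labelling", {
  set.seed(43)
  for (i in 1:25) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    dy <- orient_pair(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
    so <- shoulder_orientation(dy, "parent")$values[1]
    ro <- relative_shoulder_orientation(dy)$values[1]
    for (x in c(so, ro)) if (is.finite(x)) {
      expect_gte(x, 0); expect_lte(x, 90)
    }
    # swap left/right shoulders of the parent
    dy2 <- dy
    dy2$parent$pos[, 3, ] <- dy$parent$pos[, 4, ]
    dy2$parent$pos[, 4, ] <- dy$parent$pos[, 3, ]
    expect_equal(shoulder_orientation(dy2, "parent")$values[1], so)
    expect_equal(relative_shoulder_orientation(dy2)$values[1], ro)
  }
})

test_that("vertically stacked shoulders degrade to a gap", {
  dy <- orient_pair(c(0, 1, 0))
  expect_true(all(shoulder_orientation(dy, "parent")$gap))
})

test_that("track_speed closed forms: rest, uniform motion, time reversal", {
  clock <- make_clock(0, 1, 30)
  still <- matrix(0.3, 31, 3)
  expect_equal(track_speed(still, clock)$values, rep(0, 31))
  moving <- cbind(0.3 * clock, 0, 0)
  sp <- track_speed(moving, clock)
  expect_equal(sp$values, rep(0.3, 31), tolerance = 1e-9)
  rev_sp <- track_speed(moving[31:1, ], clock)
  expect_equal(rev_sp$values, sp$values[31:1], tolerance = 1e-9)
})

test_that("movement contribution implements the defining ratio", {
  clock <- make_clock(0, 2, 30)
  n <- length(clock)
  spd <- function(v) feature_series("s", clock, rep(v, n), scope = "x",
                                    units = "m/s")
  mc <- movement_contribution(spd(0), spd(0.2))
  expect_equal(mc$child$values, rep(1, n))
  mc2 <- movement_contribution(spd(0.1), spd(0.3))
  expect_equal(mc2$child$values, rep(0.75, n))
  expect_equal(mc2$parent$values + mc2$child$values, rep(1, n))
  mc3 <- movement_contribution(spd(1e-4), spd(2e-4))
  expect_true(all(mc3$child$gap))             # below the no-movement floor
})

test_that("contributions sum to one wherever defined (random speeds)", {
  set.seed(47)
  clock <- make_clock(0, 3, 30)
  n <- length(clock)
  sp <- feature_series("p", clock, abs(stats::rnorm(n, 0.1, 0.05)),
                       scope = "parent", units = "m/s")
  sc <- feature_series("c", clock, abs(stats::rnorm(n, 0.2, 0.05)),
                       scope = "child", units = "m/s")
  mc <- movement_contribution(sp, sc)
  ok <- !mc$parent$gap
  expect_true(any(ok))
  expect_equal(mc$parent$values[ok] + mc$child$values[ok],
               rep(1, sum(ok)))
})

test_that("approach_avoid labels a triangle wave by derivative sign", {
  clock <- make_clock(0, 8, 30)
  tri <- 0.5 + 0.3 * abs((clock %% 4) - 2) / 2    # down 2 s, up 2 s
  f <- feature_series("d", clock, tri, units = "m")
  lab <- approach_avoid(f)
  expect_equal(lab[clock > 1.2 & clock < 1.8],
               rep("approaching", sum(clock > 1.2 & clock < 1.8)))
  expect_equal(lab[clock > 3.2 & clock < 3.8],
               rep("moving_apart", sum(clock > 3.2 & clock < 3.8)))
  flat <- approach_avoid(feature_series("d", clock, rep(0.5, length(clock)),
                                        units = "m"))
  expect_true(all(flat[-seq_len(31)] == "stable"))
  mono <- approach_avoid(feature_series("d", clock, 1 - 0.05 * clock,
                                        units = "m"))
  expect_true(all(mono[-seq_len(31)] == "approaching"))
})

dip_series <- function(dips, clock, base = 0.5, low = 0.02, width = 0.4) {
  v <- rep(base, length(clock))
  for (d in dips) v[clock >= d & clock < d + width] <- low
  list(feature_series("h1", clock, v, units = "m"),
       feature_series("h2", clock, rep(base, length(clock)), units = "m"))
}

test_that("contact detection: none, one, and debounce-merged dips", {
  clock <- make_clock(0, 10, 30)
  expect_equal(nrow(count_hand_contacts(dip_series(numeric(0), clock))), 0L)
  one <- count_hand_contacts(dip_series(3, clock))
  expect_equal(nrow(one), 1L)
  expect_lt(one$min_distance, 0.1)
  expect_equal(one$start, 3, tolerance = 0.05)
  # two dips 0.1 s apart merge under a 0.25 s debounce (constructed oracle)
  merged <- count_hand_contacts(dip_series(c(3, 3.5), clock))
  expect_equal(nrow(merged), 1L)
  apart <- count_hand_contacts(dip_series(c(3, 5), clock))
  expect_equal(nrow(apart), 2L)
})

test_that("summarize_feature reports segment statistics and gaps", {
  clock <- make_clock(0, 9.9, 10)
  f <- feature_series("d", clock, rep(0.5, 100), units = "m")
  s <- summarize_feature(f, list(start = 0, end = 10))
  expect_equal(s$mean, 0.5); expect_equal(s$min, 0.5); expect_equal(s$max, 0.5)
  half <- feature_series("d", clock, c(rep(0.5, 50), rep(NA, 50)),
                         gap = c(rep(FALSE, 50), rep(TRUE, 50)), units = "m")
  s2 <- summarize_feature(half, list(start = 0, end = 10))
  expect_equal(s2$gap_fraction, 0.5)
  s3 <- summarize_feature(half, list(start = 5, end = 10))
  expect_false(s3$defined)
  # half-open [start, end): the end tick is excluded
  s4 <- summarize_feature(f, list(start = 0, end = 0.1))
  expect_equal(s4$n, 1L)
})
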