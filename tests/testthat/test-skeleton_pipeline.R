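# Identity assignment, inconsistent-frame suppression, fusion, smoothing
# and phase segmentation.

seats <- default_geometry()$seats

test_that("slots at the two seats get the right roles with high confidence", {
  p_stream <- const_stream(60, const_pose(c(0.42, 0, 0.42)), slot = 0L)
  c_stream <- const_stream(60, const_pose(c(0.28, 0, -0.28), half_width = 0.12),
                           slot = 1L)
  asg <- assign_identity(list(p_stream, c_stream), seats)
  expect_true(all(asg$role[asg$slot == 0] == "parent"))
  expect_true(all(asg$role[asg$slot == 1] == "child"))
  expect_true(all(asg$confidence > 0.3))
})

test_that("a slot midway between seats is still assigned to the nearest", {
  mid <- const_stream(30, const_pose(c(0.6, 0, 0.001)))
  asg <- assign_identity(list(mid), seats)
  expect_true(all(asg$role == "parent"))   # strictly nearest (z = +0.001)
  expect_true(all(asg$confidence < 0.05))
})

test_that("two slots claiming one seat raise AmbiguousIdentity", {
  s1 <- const_stream(120, const_pose(c(0.42, 0, 0.42)), slot = 0L)
  s2 <- const_stream(120, const_pose(c(0.38, 0, 0.38)), slot = 1L)
  expect_warning(asg <- assign_identity(list(s1, s2), seats),
                 class = "AmbiguousIdentity")
  # nearest slot keeps the seat; the other is unassigned, not re-labelled
  expect_true(all(is.na(asg$role[asg$slot == 1])))
  expect_true(all(asg$role[asg$slot == 0] == "parent"))
})

test_that("reject_inconsistent drops exactly the teleported frame", {
  st <- const_stream(30, const_pose(c(0.42, 0, 0.42)))
  st$pos[15, , 1] <- st$pos[15, , 1] + 1      # 1 m jump for one 33 ms frame
  out <- reject_inconsistent(st, seats$parent)
  expect_equal(nrow(out$log), 1L)
  expect_equal(out$log$rule, "jump")
  expect_equal(out$log$time, st$time[15])
  expect_equal(length(out$stream$time), 29L)
})

test_that("impossible shoulder widths and off-seat torsos are dropped", {
  st <- const_stream(10, const_pose(c(0.42, 0, 0.42)))
  wide <- const_pose(c(0.42, 0, 0.42)); wide[3, ] <- wide[3, ] + c(1.0, 0, 0)
  st$pos[4, , ] <- wide                        # shoulders ~1.2 m apart
  out <- reject_inconsistent(st, seats$parent)
  expect_true("shoulder_width" %in% out$log$rule)
  far <- const_stream(10, const_pose(c(3, 0, 3)))
  out2 <- reject_inconsistent(far, seats$parent)
  expect_equal(unique(out2$log$rule), "seat_radius")
  expect_equal(length(out2$stream$time), 0L)
  clean <- reject_inconsistent(const_stream(20), seats$parent)
  expect_equal(nrow(clean$log), 0L)
})

test_that("adding an outlier never causes a kept frame to be dropped", {
  set.seed(31)
  st <- const_stream(40, const_pose(c(0.42, 0, 0.42)))
  st$pos <- st$pos + array(stats::rnorm(length(st$pos), 0, 0.01), dim(st$pos))
  base_kept <- reject_inconsistent(st, seats$parent)$stream$time
  st2 <- st
  st2$pos[20, , ] <- st2$pos[20, , ] + 2      # inject an outlier
  kept2 <- reject_inconsistent(st2, seats$parent)$stream$time
  expect_true(all(setdiff(base_kept, st$time[20]) %in% kept2))
})

test_that("fusion prefers the facing sensor and never invents values", {
  clock <- make_clock(0, 1, 30)
  a <- const_stream(31, const_pose(c(0.40, 0, 0.40)))
  b <- const_stream(31, const_pose(c(0.40, 0, 0.40)))
  b$pos <- b$pos + 0.005                      # sensors agree within 1 cm
  fused <- fuse_streams(a, b, clock, facing = "A")
  expect_true(all(fused$provenance[!fused$gap] == "A"))
  expect_true(all(fused$pos[, , 1][!fused$gap] %in% a$pos[, , 1]))
  fusedB <- fuse_streams(a, b, clock, facing = "B")
  expect_true(all(fusedB$provenance[!fusedB$gap] == "B"))
})

test_that("one-sensor coverage and disagreement are handled per tick", {
  clock <- make_clock(0, 1, 30)
  a <- const_stream(31, const_pose(c(0.40, 0, 0.40)))
  fused <- fuse_streams(a, NULL, clock, facing = "B")
  expect_true(all(fused$provenance[!fused$gap] == "A"))
  expect_false(any(fused$gap))
  b <- const_stream(31, const_pose(c(0.40, 0, 0.40)))
  b$pos[16, , 1] <- b$pos[16, , 1] + 0.4      # 0.4 m disagreement on one tick
  fused2 <- fuse_streams(a, b, clock, facing = "A")
  expect_true(all(fused2$gap[16, ]))
  expect_equal(sort(unique(fused2$disagreements$tick)), 16)
  expect_false(any(fused2$gap[-16, ]))
})

test_that("smoothing: identity window, constants, and the step ramp", {
  dy <- const_dyad(30)
  expect_equal(smooth_dyad(dy, 1), dy)
  expect_equal(smooth_dyad(dy, 5)$parent$pos, dy$parent$pos)
  expect_error(smooth_dyad(dy, 4), class = "InvalidWindow")
  # unit step in x -> 5-sample ramp with values k/5 (hand-computed oracle)
  dy2 <- const_dyad(40)
  step <- as.numeric(seq_len(40) > 20)
  dy2$parent$pos[, 1, 1] <- dy2$parent$pos[, 1, 1] + step
  sm <- smooth_dyad(dy2, 5)
  got <- sm$parent$pos[, 1, 1] - dy2$parent$pos[1, 1, 1]
  expect_equal(got[19:23], c(1, 2, 3, 4, 5) / 5)
  expect_equal(got[c(10, 30)], c(0, 1))
})

test_that("smoothing skips gaps and commutes with global translation", {
  dy <- const_dyad(30)
  dy$parent$pos[10:12, 3, ] <- NA
  dy$parent$gap[10:12, 3] <- TRUE
  sm <- smooth_dyad(dy, 5)
  expect_true(all(is.na(sm$parent$pos[10:12, 3, 1])))
  expect_true(all(is.finite(sm$parent$pos[c(9, 13), 3, 1])))
  dy_t <- dy
  dy_t$parent$pos <- dy$parent$pos + 1.23
  dy_t$child$pos <- dy$child$pos + 1.23
  sm_t <- smooth_dyad(dy_t, 5)
  expect_equal(sm_t$parent$pos, sm$parent$pos + 1.23)
})

test_that("segment_phases lays out the protocol plan", {
  man <- default_geometry()
  seg <- segment_phases(man, 480)
  expect_equal(seg$start, c(0, 240, 360))
  expect_equal(seg$end, c(240, 360, 480))
  expect_warning(seg2 <- segment_phases(man, 300))
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$end, c(240, 300))
  one <- session_manifest(data.frame(name = "only", duration = 60),
                          man$seats)
  expect_equal(segment_phases(one, 100), data.frame(name = "only",
                                                    start = 0, end = 60))
  suppressWarnings(expect_error(segment_phases(man, 0), class = "EmptySegment"))
})
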