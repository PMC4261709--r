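# Bundle dialect round-trips, error cases, and gap-aware resampling.

make_tiny_bundle <- function(seed = 3, duration = 6) {
  generate_recording(quick_profile(), duration = duration, seed = seed)
}

test_that("write_bundle / read_bundle round-trips all fields", {
  b <- make_tiny_bundle()
  dir <- file.path(tempdir(), "rt_bundle")
  write_bundle(b$recordings, b$manifest, dir, ground_truth = NULL)
  back <- read_bundle(dir)
  for (sid in c("A", "B")) {
    orig <- b$recordings[[sid]]; got <- back$recordings[[sid]]
    expect_equal(length(got$skeletons), length(orig$skeletons))
    for (k in seq_along(orig$skeletons)) {
      expect_equal(got$skeletons[[k]]$time, orig$skeletons[[k]]$time,
                   tolerance = 1e-6)
      expect_lt(max(abs(got$skeletons[[k]]$pos - orig$skeletons[[k]]$pos),
                    na.rm = TRUE), 1e-9)
      expect_identical(got$skeletons[[k]]$state, orig$skeletons[[k]]$state)
      expect_identical(got$skeletons[[k]]$slot, orig$skeletons[[k]]$slot)
    }
    # audio exact up to one 16-bit quantisation step
    expect_lt(max(abs(got$audio$samples - orig$audio$samples)), 1 / 32767)
    expect_identical(got$audio$rate, orig$audio$rate)
    expect_equal(got$source_angle$azimuth, orig$source_angle$azimuth,
                 tolerance = 1e-3)
    expect_lt(max(abs(got$calibration$points - orig$calibration$points)), 1e-9)
    expect_identical(got$calibration$rows, 3L)
  }
  expect_equal(back$manifest$phases, b$manifest$phases)
  expect_equal(back$manifest$seats, b$manifest$seats)
  unlink(dir, recursive = TRUE)
})

test_that("writing the same bundle twice is byte-identical", {
  b <- make_tiny_bundle()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_bundle(b$recordings, b$manifest, d1)
  write_bundle(b$recordings, b$manifest, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("incomplete and malformed bundles are rejected with named errors", {
  b <- make_tiny_bundle()
  dir <- file.path(tempdir(), "bad_bundle")
  write_bundle(b$recordings, b$manifest, dir)
  file.remove(file.path(dir, "sensorB", "audio.wav"))
  expect_error(read_bundle(dir), class = "BundleIncomplete")
  expect_error(read_bundle(file.path(tempdir(), "no_such_dir")),
               class = "BundleIncomplete")
  # decreasing timestamps in a skeleton file
  write_bundle(b$recordings, b$manifest, dir)
  sk <- file.path(dir, "sensorA", "skeleton.xml")
  txt <- readLines(sk)
  ts <- grep("<frame ", txt)
  txt[ts[2]] <- sub('t="[0-9.]+"', 't="0.000001"', txt[ts[2]])
  txt[ts[3]] <- sub('t="[0-9.]+"', 't="0.000000"', txt[ts[3]])
  writeLines(txt, sk)
  err <- tryCatch(read_bundle(dir), error = identity)
  expect_s3_class(err, "ParseError")
  expect_match(conditionMessage(err), "skeleton.xml")
  unlink(dir, recursive = TRUE)
})

test_that("an empty skeleton stream survives a round-trip", {
  b <- make_tiny_bundle()
  b$recordings$A$skeletons <- list(skeleton_stream(numeric(0),
    array(numeric(0), c(0, 10, 3)), slot = 0L))
  dir <- file.path(tempdir(), "empty_stream")
  write_bundle(b$recordings, b$manifest, dir)
  back <- read_bundle(dir)
  expect_length(back$recordings$A$skeletons, 0L)
  unlink(dir, recursive = TRUE)
})

test_that("skeleton_stream enforces its invariants", {
  pos <- array(0, c(2, 10, 3))
  expect_error(skeleton_stream(c(1, 0.5), pos), class = "ParseError")
  expect_error(skeleton_stream(c(0, NA), pos), class = "ParseError")
  st <- skeleton_stream(c(0, 1), pos)
  expect_s3_class(st, "skeleton_stream")
})

test_that("resample_to_clock is the identity on clock-aligned streams", {
  clock <- make_clock(0, 2, 30)
  vals <- sin(clock)
  rs <- resample_to_clock(clock, vals, clock, max_gap = 0.05)
  expect_identical(rs$values, vals)
  expect_false(any(rs$gap))
})

test_that("resample_to_clock marks holes as gaps (brute-force oracle)", {
  set.seed(11)
  t_in <- sort(c(seq(0, 3, by = 1 / 30), seq(5, 8, by = 1 / 30)))  # 2 s hole
  vals <- stats::rnorm(length(t_in))
  clock <- make_clock(0, 8, 30)
  max_gap <- 0.05
  rs <- resample_to_clock(t_in, vals, clock, max_gap)
  # oracle: a tick is covered iff some input sample lies within max_gap
  covered <- vapply(clock, function(ti) any(abs(t_in - ti) <= max_gap + 1e-12),
                    logical(1))
  expect_identical(rs$gap, !covered)
  n_hole <- sum(clock > 3 + max_gap & clock < 5 - max_gap)
  expect_equal(sum(rs$gap), n_hole)
  # never fabricates: every emitted value is exactly one input value
  expect_true(all(rs$values[!rs$gap] %in% vals))
})

test_that("resample_to_clock handles degenerate streams", {
  clock <- make_clock(0, 1, 30)
  rs <- resample_to_clock(0.5, 7, clock, max_gap = 0.05)
  expect_equal(unique(rs$values[!rs$gap]), 7)
  expect_equal(sum(!rs$gap), sum(abs(clock - 0.5) <= 0.05 + 1e-12))
  expect_error(resample_to_clock(0.5, 7, numeric(0)), class = "EmptyClock")
  rs0 <- resample_to_clock(numeric(0), numeric(0), clock)
  expect_true(all(rs0$gap))
})

test_that("WAV files round-trip within quantisation", {
  x <- sin(2 * pi * 440 * seq(0, 0.05, by = 1 / 8000)) * 0.8
  f <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f)
  back <- read_wav(f)
  expect_equal(back$rate, 8000L)
  expect_lt(max(abs(back$samples - x)), 1 / 32767)
  unlink(f)
})
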