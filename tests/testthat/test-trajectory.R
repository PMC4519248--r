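test_that("trajectory construction validates its invariants", {
  fr <- data.frame(frame = 0:2, x = c(1, 1.2, 1.4), y = c(1, 1, 1))
  tr <- trajectory(fr, fps = 25, tank_width_cm = 18, tank_height_cm = 24,
                   body_length_cm = 4)
  expect_s3_class(tr, "fq_trajectory")
  expect_equal(nrow(tr$frames), 3)

  expect_error(trajectory(fr[c(2, 1, 3), ], fps = 25, tank_width_cm = 18,
                          tank_height_cm = 24, body_length_cm = 4),
               "strictly increasing")
  bad <- fr; bad$x[2] <- 30
  expect_error(trajectory(bad, fps = 25, tank_width_cm = 18,
                          tank_height_cm = 24, body_length_cm = 4),
               "outside")
  expect_error(trajectory(fr, fps = 0, tank_width_cm = 18,
                          tank_height_cm = 24, body_length_cm = 4))
  expect_error(trajectory(fr, fps = 25, tank_width_cm = 18,
                          tank_height_cm = 24, body_length_cm = -1))
  # a frame with one missing coordinate becomes fully missing
  half <- fr; half$x[2] <- NA
  tr2 <- trajectory(half, fps = 25, tank_width_cm = 18,
                    tank_height_cm = 24, body_length_cm = 4)
  expect_true(is.na(tr2$frames$y[2]))
})

test_that("write -> read round-trips a simulated trajectory exactly", {
  cfg <- cohort_preset("wt_9mpf", duration_s = 120)
  tr <- simulate_fish(cfg, seed = 99)
  # knock out a few coordinates to exercise the missing-marker round trip
  tr$frames$x[c(10, 500)] <- NA
  tr$frames$y[c(10, 500)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  meta <- list(fps = cfg$fps, tank_width_cm = cfg$tank_width_cm,
               tank_height_cm = cfg$tank_height_cm,
               body_length_cm = cfg$body_length_cm,
               genotype = cfg$genotype, age_group = cfg$age_group)
  write_trajectory(tr, path)
  back <- read_trajectory(path, meta)
  expect_equal(back$frames$x, tr$frames$x, tolerance = 0)
  expect_equal(back$frames$y, tr$frames$y, tolerance = 0)
  expect_equal(back$frames$frame, tr$frames$frame)
  expect_equal(back$genotype, tr$genotype)
})

test_that("malformed trajectory files are rejected with a line reference", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "0,1.0,1.0", "1,oops,1.0"), path)
  meta <- list(fps = 25, tank_width_cm = 18, tank_height_cm = 24,
               body_length_cm = 4)
  expect_error(read_trajectory(path, meta), "line 2")
})

test_that("cohort metadata files parse as typed key-value pairs", {
  path <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("fps: 25", "tank_width_cm: 18", "tank_height_cm: 24",
               "body_length_cm: 4", "genotype: HT", "age_group: 9mpf"), path)
  meta <- read_cohort_metadata(path)
  expect_identical(meta$fps, 25)
  expect_identical(meta$genotype, "HT")
})

test_that("fill_gaps interpolates short runs and flags long ones", {
  fr <- data.frame(frame = 0:2, x = c(0, NA, 2), y = c(0, NA, 2))
  tr <- trajectory(fr, fps = 25, tank_width_cm = 10, tank_height_cm = 10,
                   body_length_cm = 2)
  out <- fill_gaps(tr, max_gap_frames = 5)
  expect_equal(out$frames$x[2], 1)
  expect_equal(out$frames$y[2], 1)
  expect_equal(attr(out, "gap_report")$action, "interpolated")

  n <- 30
  fr2 <- data.frame(frame = 0:(n - 1), x = runif(n, 0, 10),
                    y = runif(n, 0, 10))
  fr2$x[10:19] <- NA; fr2$y[10:19] <- NA
  tr2 <- trajectory(fr2, fps = 25, tank_width_cm = 10, tank_height_cm = 10,
                    body_length_cm = 2)
  out2 <- fill_gaps(tr2, max_gap_frames = 5)
  expect_true(all(is.na(out2$frames$x[10:19])))
  expect_equal(attr(out2, "gap_report")$action, "excluded")
  expect_equal(attr(out2, "gap_report")$n_frames, 10)
})

test_that("fill_gaps never alters tracked coordinates and report partitions the missing set", {
  set.seed(4)
  for (rep in 1:20) {
    tr <- random_trajectory(200, miss_prob = 0.15, W = 10, H = 10)
    miss_before <- which(is.na(tr$frames$x))
    tracked <- !is.na(tr$frames$x)
    out <- fill_gaps(tr, max_gap_frames = 3)
    expect_identical(out$frames$x[tracked], tr$frames$x[tracked])
    expect_identical(out$frames$y[tracked], tr$frames$y[tracked])
    rep_tab <- attr(out, "gap_report")
    covered <- unlist(mapply(seq, rep_tab$start_frame, rep_tab$end_frame,
                             SIMPLIFY = FALSE))
    expect_setequal(covered, tr$frames$frame[miss_before])
    expect_equal(sum(rep_tab$n_frames), length(miss_before))
  }
})

test_that("a gapless trajectory passes through fill_gaps unchanged", {
  tr <- random_trajectory(100, W = 10, H = 10)
  out <- fill_gaps(tr, max_gap_frames = 5)
  expect_identical(out$frames, tr$frames)
  expect_equal(nrow(attr(out, "gap_report")), 0)
})
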