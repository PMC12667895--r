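test_that("node sets validate labels and anchor", {
  expect_s3_class(default_node_set(), "node_set")
  expect_s3_class(reduced_node_set(), "node_set")
  expect_error(node_set(c("a", "a"), "a"), class = "prelever_schema_error")
  expect_error(node_set(c("a", "b"), "c"), class = "prelever_schema_error")
})

test_that("a 3-frame table round-trips through the delimited dialect", {
  tr <- make_track(list(nose = cbind(0:2, 0:2)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  back <- read_track_csv(path, reduced_node_set())
  expect_equal(node_positions(back, "nose"),
               cbind(x = as.numeric(0:2), y = as.numeric(0:2)))
  expect_equal(n_frames(back), 3L)
})

test_that("write-then-read preserves simulated coordinates bit-exactly", {
  p <- trajectory_params(seed = 11, dropout_p = 0.05)
  tr <- simulate_trajectory(p, n_frames = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  back <- read_track_csv(path, default_node_set())
  for (nm in tr$nodes$names) {
    expect_identical(node_positions(back, nm), node_positions(tr, nm),
                     label = nm)
  }
})

test_that("frame-index gaps and schema problems are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- make_track(list(nose = cbind(0:3, 0:3)))
  write_track_csv(tr, path)
  txt <- readLines(path)
  writeLines(txt[-3], path)  # drop frame 1 -> 0,2,3
  expect_error(read_track_csv(path, reduced_node_set()),
               class = "prelever_format_error")
  expect_error(read_track_csv(withr::local_tempfile(), reduced_node_set()),
               class = "prelever_read_error")
  # a node the file does not carry
  writeLines(txt, path)
  expect_error(read_track_csv(path, default_node_set()),
               class = "prelever_schema_error")
})

test_that("interpolation fills interior gaps linearly and holds edges", {
  nose <- cbind(c(0, NA, 2), c(0, NA, 4))
  tr <- interpolate_missing(make_track(list(nose = nose)))
  expect_equal(node_positions(tr, "nose")[2, ], c(x = 1, y = 2))

  nose2 <- cbind(c(NA, NA, 5, 7), c(NA, NA, 5, 7))
  tr2 <- interpolate_missing(make_track(list(nose = nose2)))
  expect_equal(node_positions(tr2, "nose")[1:2, ],
               cbind(x = c(5, 5), y = c(5, 5)))
})

test_that("interpolation is the identity on complete tracks and idempotent", {
  full <- make_track(list(nose = cbind(1:5, 5:1)))
  expect_identical(interpolate_missing(full)$coords, full$coords)
  for (seed in 1:5) {
    set.seed(seed)
    v <- cbind(rnorm(50), rnorm(50))
    v[sample(50, 12), ] <- NA
    tr <- make_track(list(nose = v))
    once <- interpolate_missing(tr)
    expect_identical(interpolate_missing(once)$coords, once$coords)
    expect_false(anyNA(once$coords))
  }
})

test_that("a never-observed node is an irreparable track", {
  nose <- cbind(rep(NA_real_, 4), rep(NA_real_, 4))
  expect_error(interpolate_missing(make_track(list(nose = nose))),
               class = "prelever_irreparable_track_error")
  expect_error(interpolate_missing(make_track(list(nose = nose))),
               regexp = "nose")
})

test_that("calibration averages per-measurement ratios", {
  expect_equal(compute_cm_per_px(30, 270), 30 / 270)
  # ratios 0.10, 0.11, 0.11, 0.12, 0.11 -> mean 0.11
  known <- c(10, 11, 11, 12, 11)
  px <- rep(100, 5)
  expect_equal(compute_cm_per_px(known, px), 0.11)
  expect_equal(compute_cm_per_px(rep(2.5, 3), rep(10, 3)), 0.25)
  expect_error(compute_cm_per_px(c(30, -1), c(270, 10)),
               class = "prelever_domain_error")
})

test_that("calibration is order-invariant and scales linearly", {
  set.seed(7)
  for (i in 1:10) {
    known <- runif(5, 5, 40)
    px <- runif(5, 50, 400)
    o <- sample(5)
    expect_equal(compute_cm_per_px(known, px),
                 compute_cm_per_px(known[o], px[o]))
    expect_equal(compute_cm_per_px(2 * known, px),
                 2 * compute_cm_per_px(known, px))
  }
  spec <- calibration_spec(c(30, 30, 18), c(270, 265, 160))
  expect_equal(spec$cm_per_px,
               mean(c(30 / 270, 30 / 265, 18 / 160)))
})

test_that("lever-extension alignment slices and re-indexes both segments", {
  n <- 18000
  ramp <- cbind(seq_len(n) - 1, rep(0, n))  # x encodes the original frame
  tr <- make_track(list(nose = ramp), n = n)
  segs <- align_to_lever_extension(tr, 9000, segment_len = 7500)
  expect_equal(n_frames(segs$pre), 7500)
  expect_equal(n_frames(segs$post), 7500)
  expect_equal(node_positions(segs$pre, "nose")[, "x"],
               as.numeric(1500:8999))
  expect_equal(node_positions(segs$post, "nose")[, "x"],
               as.numeric(9000:16499))
  expect_equal(segs$pre$coords$frame, 0:7499)
  expect_equal(segs$post$coords$frame, 0:7499)
})

test_that("alignment truncates with a warning, never a hard failure", {
  tr <- make_track(list(nose = cbind(1:100, 1:100)))
  expect_warning(
    segs <- align_to_lever_extension(tr, 0, segment_len = 50),
    class = "prelever_truncation_warning")
  expect_equal(n_frames(segs$pre), 0)
  expect_equal(n_frames(segs$post), 50)
  # lengths are min(segment_len, available) on each side
  for (ext in c(10, 40, 90)) {
    segs <- suppressWarnings(
      align_to_lever_extension(tr, ext, segment_len = 50))
    expect_equal(n_frames(segs$pre), min(50, ext))
    expect_equal(n_frames(segs$post), min(50, 100 - ext))
  }
})

test_that("noncontingent recordings are routed away from alignment", {
  tr <- make_track(list(nose = cbind(1:10, 1:10)))
  expect_error(align_to_lever_extension(tr, NA),
               class = "prelever_contract_error")
})

test_that("run config round-trips through YAML with defaults filled", {
  cfg <- read_run_config()
  expect_equal(cfg$cm_per_px, mean(c(30 / 270, 30 / 270, 18 / 162,
                                     18 / 162, 18 / 162)))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(frame_rate = 30, smooth_window = 10), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$frame_rate, 30)
  expect_equal(cfg2$zone_half_x, 30)
})
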