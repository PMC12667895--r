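test_that("trajectory parameters are validated", {
  expect_error(trajectory_params(persistence = 1),
               class = "prelever_parameter_error")
  expect_error(trajectory_params(lever_attraction = 1.5),
               class = "prelever_parameter_error")
  expect_error(trajectory_params(locomotor_gain = 0),
               class = "prelever_parameter_error")
  expect_error(trajectory_params(dropout_p = 1),
               class = "prelever_parameter_error")
  zones <- default_zones()
  zones$active_lever <- c(-10, 50)
  expect_error(simulate_trajectory(trajectory_params(), 10, zones = zones),
               class = "prelever_parameter_error")
})

test_that("the same seed reproduces a track bit-identically", {
  p <- trajectory_params(seed = 77, dropout_p = 0.03)
  a <- simulate_trajectory(p, n_frames = 400)
  b <- simulate_trajectory(p, n_frames = 400)
  expect_identical(a$coords, b$coords)
  p2 <- p
  p2$seed <- 78L
  c <- simulate_trajectory(p2, n_frames = 400)
  expect_false(identical(a$coords, c$coords))
})

test_that("a frozen walker travels (almost) nowhere", {
  p <- trajectory_params(step_scale = 0, lever_attraction = 0,
                         dropout_p = 0, seed = 5)
  tr <- simulate_trajectory(p, n_frames = 500, jitter_sd = 0)
  expect_equal(path_length(node_positions(tr, "catheter"), 0.111), 0,
               tolerance = 1e-9)
})

test_that("dropout hits roughly its nominal per-frame rate", {
  p <- trajectory_params(dropout_p = 0.1, seed = 9)
  tr <- simulate_trajectory(p, n_frames = 5000)
  frac <- mean(is.na(tr$coords$nose.x))
  expect_lt(abs(frac - 0.1), 0.02)
  expect_false(anyNA(interpolate_missing(tr)$coords))
})

test_that("simulated tracks pass validation and the metrics pipeline", {
  p <- trajectory_params(seed = 21, dropout_p = 0.05)
  tr <- simulate_trajectory(p, n_frames = 1000)
  expect_s3_class(tr, "pose_track")
  res <- sim_session_metrics(0.3, seed = 21, nf = 1000, dropout_p = 0.05)
  expect_gt(res["loco"], 0)
  expect_gte(res["entrances"], 0)
})

test_that("press streams respect the schedule and the lockout", {
  expect_equal(nrow(simulate_sa_session(0, 2, seed = 1)), 0)
  ev <- simulate_sa_session(8, 2, seed = 4)
  expect_gt(nrow(ev), 50)
  # pump (6 s) + timeout (20 s) separate every pair of infusions
  expect_true(all(diff(ev$time_s) >= 26))
  expect_false(any(ev$shocked))

  pr <- simulate_sa_session(30, 6, schedule = "PR", seed = 6)
  expect_equal(pr$ratio_completed,
               pr_requirement(seq_len(nrow(pr))))
})

test_that("shock sessions pair infusions at the configured probability", {
  tot <- 0L
  hit <- 0L
  seed <- 100L
  while (tot < 40000L) {
    ev <- simulate_sa_session(10, 1, shock_session = TRUE, seed = seed)
    tot <- tot + nrow(ev)
    hit <- hit + sum(ev$shocked)
    seed <- seed + 1L
  }
  expect_lt(abs(hit / tot - 0.30), 0.01)
})

test_that("noncontingent drug gain raises path length; unit gain does not", {
  loco_pair <- function(seed, gain) {
    params <- list(
      baseline = trajectory_params(seed = seed, dropout_p = 0),
      saline = trajectory_params(seed = seed + 500, dropout_p = 0),
      drug = trajectory_params(seed = seed + 1000, dropout_p = 0))
    s <- simulate_noncontingent_session(params, drug_gain = gain,
                                        n_frames = 1200)
    c(base = path_length(node_positions(s$baseline, "catheter"), 0.111),
      drug = path_length(node_positions(s$drug, "catheter"), 0.111))
  }
  doubled <- sapply(1:15, loco_pair, gain = 2)
  expect_gt(mean(doubled["drug", ]), mean(doubled["base", ]))
  null <- sapply(101:130, loco_pair, gain = 1)
  # same generative law: a two-sample test should not reject at alpha 0.01
  expect_gt(t.test(null["drug", ], null["base", ])$p.value, 0.01)
})

test_that("phase tracks differ when their seeds differ", {
  params <- list(baseline = trajectory_params(seed = 1),
                 saline = trajectory_params(seed = 2),
                 drug = trajectory_params(seed = 3))
  s <- simulate_noncontingent_session(params, n_frames = 200)
  expect_false(identical(s$baseline$coords, s$saline$coords))
  expect_false(identical(s$saline$coords, s$drug$coords))
})

test_that("lever attraction raises entrances per meter", {
  high <- sapply(1:12, function(s) {
    sim_session_metrics(0.6, seed = s, nf = 2000)["epm"]
  })
  low <- sapply(1:12, function(s) {
    sim_session_metrics(0, seed = s + 300, nf = 2000)["epm"]
  })
  expect_gt(mean(high), mean(low))
})

test_that("seed derivation is stable, distinct, and in 31-bit range", {
  a <- derive_seed(1, "R001", "ShortAccess01")
  expect_identical(a, derive_seed(1, "R001", "ShortAccess01"))
  expect_false(a == derive_seed(1, "R001", "ShortAccess02"))
  expect_false(a == derive_seed(2, "R001", "ShortAccess01"))
  seeds <- vapply(1:200, function(i) {
    derive_seed(1, sprintf("R%03d", i), "LongAccess05")
  }, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("a reduced fixture set writes the expected tree deterministically", {
  tl <- default_timeline()
  keep <- tl$session_label %in% c("ShortAccess01", "ShortAccess02",
                                  "ShortAccess03")
  spec <- fixture_spec(n_subjects = 4, timeline = tl[keep, ],
                       n_frames = 40, master_seed = 3L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- build_fixture_set(spec, d1)
  m2 <- build_fixture_set(spec, d2)
  expect_equal(attr(m1, "n_sa_files"), 12L)
  expect_equal(length(list.files(file.path(d1, "tracks"))), 12L)
  expect_identical(
    unname(tools::md5sum(file.path(d1, m1$track_path))),
    unname(tools::md5sum(file.path(d2, m2$track_path))))
  # manifest reparses and the tracks reparse to the generated coordinates
  man <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 12L)
  p <- spec$base_params
  p$seed <- derive_seed(3L, "R002", "ShortAccess02")
  regen <- simulate_trajectory(p, n_frames = 40)
  ondisk <- read_track_csv(
    file.path(d1, man$track_path[man$subject_id == "R002" &
                                   man$session_label == "ShortAccess02"]),
    default_node_set())
  expect_identical(ondisk$coords, regen$coords)
})

test_that("excluded files are written but flagged", {
  tl <- default_timeline()
  keep <- tl$session_label %in% c("ShortAccess01", "ShortAccess02")
  spec <- fixture_spec(n_subjects = 2, timeline = tl[keep, ],
                       n_frames = 30,
                       exclude = "R001/ShortAccess02", master_seed = 9L)
  d <- withr::local_tempdir()
  m <- build_fixture_set(spec, d)
  expect_equal(sum(m$excluded), 1L)
  expect_true(file.exists(file.path(
    d, m$track_path[m$excluded])))
})
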