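test_that("percent difference from baseline", {
  expect_equal(percent_diff_baseline(10, 10), 0)
  expect_equal(percent_diff_baseline(15, 10), 50)
  expect_true(is.na(percent_diff_baseline(3, 0)))
  expect_equal(percent_diff_baseline(c(1, 2, 3), 2), c(-50, 0, 50))
})

test_that("group-baseline normalization", {
  expect_equal(normalize_by_group_baseline_mean(rep(4, 5), c(4, 4)),
               rep(0, 5))
  expect_equal(normalize_by_group_baseline_mean(3, c(1, 3)), 50)
  v <- c(5, 1, 9, 2)
  o <- c(3, 1, 4, 2)
  expect_equal(normalize_by_group_baseline_mean(v[o], c(2, 2)),
               normalize_by_group_baseline_mean(v, c(2, 2))[o])
  expect_error(normalize_by_group_baseline_mean(1, c(NA_real_, NA_real_)),
               class = "prelever_contract_error")
})

test_that("upper winsorization caps at the empirical 95th percentile", {
  expect_equal(winsorize_upper(rep(7, 10)), rep(7, 10))
  x <- as.numeric(1:100)
  w <- winsorize_upper(x, 0.95)
  cap <- quantile(x, 0.95, names = FALSE)  # linear-interpolation quantile
  expect_equal(max(w), cap)
  expect_equal(w[x <= cap], x[x <= cap])
  expect_true(all(w[x > cap] == cap))
  expect_error(winsorize_upper(x, 1.2), class = "prelever_parameter_error")
  expect_error(winsorize_upper(c(1, NA, NA)),
               class = "prelever_contract_error")
})

test_that("winsorization is a monotone bound preserving ranks and minima", {
  set.seed(12)
  for (i in 1:20) {
    x <- rlnorm(50)
    w <- winsorize_upper(x)
    expect_true(all(w <= x))
    expect_lte(mean(w), mean(x))
    expect_equal(min(w), min(x))
    un <- w < max(w)
    expect_equal(order(w[un]), order(x[un]))
  }
})

test_that("composite z-score averages sessions, standardizes, and splits", {
  # loco and epm means anti-aligned across 4 subjects: z's cancel pairwise
  df <- expand.grid(subject_id = sprintf("S%d", 1:4),
                    session_label = c("ShortAccess07", "ShortAccess08",
                                      "ShortAccess09"),
                    stringsAsFactors = FALSE)
  df$loco_m <- rep(c(1, 2, 3, 4), 3)
  df$epm <- rep(c(4, 3, 2, 1), 3)
  sc <- composite_prelever_zscore(df)
  expect_equal(sc$composite, rep(0, 4))
  expect_equal(sc$group, rep("High", 4))  # ties at the median are High
  expect_equal(mean(sc$z_loco), 0, tolerance = 1e-9)
  expect_equal(sd(sc$z_loco), 1, tolerance = 1e-9)
  expect_equal(sd(sc$z_epm), 1, tolerance = 1e-9)
})

test_that("a 37-subject cohort with distinct composites splits 19/18", {
  set.seed(101)
  df <- expand.grid(subject_id = sprintf("R%02d", 1:37),
                    session_label = c("ShortAccess07", "ShortAccess08",
                                      "ShortAccess09"),
                    stringsAsFactors = FALSE)
  df$loco_m <- runif(nrow(df), 5, 40)
  df$epm <- runif(nrow(df), 0.5, 8)
  sc <- composite_prelever_zscore(df)
  expect_equal(anyDuplicated(sc$composite), 0L)
  expect_equal(sum(sc$group == "High"), 19)
  expect_equal(sum(sc$group == "Low"), 18)
})

test_that("composite labels are invariant to affine rescaling and the
           split is ceil(n/2) for distinct scores", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(c(6, 11, 20), 1)
    df <- expand.grid(subject_id = sprintf("S%02d", seq_len(n)),
                      session_label = c("ShortAccess07", "ShortAccess08",
                                        "ShortAccess09"),
                      stringsAsFactors = FALSE)
    df$loco_m <- rlnorm(nrow(df), 2)
    df$epm <- rlnorm(nrow(df))
    sc <- composite_prelever_zscore(df)
    if (anyDuplicated(sc$composite) == 0L) {
      expect_equal(sum(sc$group == "High"), ceiling(n / 2))
    }
    df2 <- df
    df2$loco_m <- 3.7 * df$loco_m + 12   # meters -> arbitrary affine units
    df2$epm <- 0.2 * df$epm + 1
    sc2 <- composite_prelever_zscore(df2)
    expect_equal(sc2$group, sc$group)
    expect_equal(sc2$composite, sc$composite, tolerance = 1e-9)
  }
})

test_that("missing window sessions average over what exists; degenerate
           cohorts error", {
  df <- data.frame(
    subject_id = c("A", "A", "B"),
    session_label = c("ShortAccess07", "ShortAccess08", "ShortAccess07"),
    loco_m = c(10, 20, 30), epm = c(1, 3, 5))
  sc <- composite_prelever_zscore(df)
  expect_equal(sc$mean_loco[sc$subject_id == "A"], 15)
  expect_equal(sc$n_sessions, c(2L, 1L))

  same <- data.frame(subject_id = c("A", "B"),
                     session_label = "ShortAccess07",
                     loco_m = c(5, 5), epm = c(1, 2))
  expect_error(composite_prelever_zscore(same),
               class = "prelever_degenerate_cohort_error")
})

test_that("expression labels partition the cohort by locomotion change", {
  d <- data.frame(subject_id = c("A", "B", "C", "D"),
                  drug01 = c(0, 0, 0, 0),
                  drug03 = c(25, -40, 0, NA))
  cl <- classify_expression(d)
  expect_equal(cl$label,
               c("Sensitization", "Tolerance", "Unclassified",
                 "Unclassified"))
  set.seed(8)
  for (i in 1:10) {
    n <- 30
    d <- data.frame(subject_id = seq_len(n), drug01 = 0,
                    drug03 = rnorm(n))
    cl <- classify_expression(d)
    expect_equal(sum(cl$label == "Sensitization"), sum(d$drug03 > 0))
    expect_equal(nrow(cl), sum(table(cl$label)))
  }
})

test_that("abstinence codes map gaps to 18/66/90 within a 6-hour band", {
  end <- as.POSIXct("2023-01-02 14:00", tz = "UTC")  # 6-h session ended
  nxt <- as.POSIXct("2023-01-03 08:00", tz = "UTC")
  code <- encode_abstinence(end, nxt)
  expect_equal(code$hours, 18)
  expect_equal(code$category, "18")

  fri_end <- as.POSIXct("2023-01-06 14:00", tz = "UTC")
  mon <- as.POSIXct("2023-01-09 08:00", tz = "UTC")
  expect_equal(encode_abstinence(fri_end, mon)$category, "66")

  tue <- as.POSIXct("2023-01-10 08:00", tz = "UTC")
  expect_equal(encode_abstinence(fri_end, tue)$category, "90")

  gap40 <- encode_abstinence(end, end + 40 * 3600)
  expect_equal(gap40$category, "other")

  # 2-h short-access sessions at fixed start times give 22-h gaps:
  # still the consecutive-day code
  sha_end <- as.POSIXct("2023-01-02 10:00", tz = "UTC")
  expect_equal(encode_abstinence(sha_end, nxt)$category, "18")

  expect_error(encode_abstinence(nxt, end), class = "prelever_manifest_error")
})

test_that("abstinence codes run along a subject's manifest", {
  m <- data.frame(
    subject_id = "A",
    session_label = c("LongAccess01", "LongAccess02", "LongAccess03"),
    duration_h = 6,
    start = as.POSIXct(c("2023-01-05 08:00", "2023-01-06 08:00",
                         "2023-01-09 08:00"), tz = "UTC"))
  ac <- abstinence_codes(m)
  expect_equal(ac$session_label, c("LongAccess02", "LongAccess03"))
  expect_equal(ac$category, c("18", "66"))
})
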