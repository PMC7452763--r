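test_that("bin_size applies the three size-region rules", {
  expect_equal(bin_size(850), 850)
  expect_equal(bin_size(1000), 1000)      # boundary: still unbinned region
  expect_equal(bin_size(1001), 1010)      # rounded *up* to the next 10
  expect_equal(bin_size(1010), 1010)
  expect_equal(bin_size(9996), 10000)
  expect_equal(bin_size(10349), 10300)    # nearest 100, half-up ties
  expect_equal(bin_size(10350), 10400)
  expect_error(bin_size(0), "> 0")
  expect_error(bin_size(c(100, -5)), "> 0")
})

test_that("equal bins are averaged, then negatives clipped (order configurable)", {
  tr <- make_trace("s1", c(1001, 1003), c(2, 4))
  m <- merge_traces(tr)
  expect_equal(m$size_bp, 1010)
  expect_equal(m$rfu, 3)

  tr2 <- make_trace("s1", c(300, 1001, 1003), c(-5, -5, 5))
  after <- merge_traces(tr2, clip = "after")
  expect_equal(after$rfu, c(0, 0))        # mean(-5, 5) = 0 post-clip
  before <- merge_traces(tr2, clip = "before")
  expect_equal(before$rfu, c(0, 2.5))     # clip first: mean(0, 5)
  expect_true(all(after$rfu >= 0) && all(before$rfu >= 0))
})

test_that("merging is idempotent on an already-binned grid and never adds points", {
  sizes <- c(200, 800, 1010, 1500, 9990, 10400, 25000)
  tr <- make_trace("s1", sizes, c(1, 2, 3, 4, 5, 6, 7))
  m <- merge_traces(tr)
  expect_equal(m$size_bp, sizes)
  expect_equal(m$rfu, tr$rfu)
  set.seed(1)
  for (i in 1:5) {
    s <- sort(runif(80, 50, 59000))
    mi <- merge_traces(make_trace("x", s, rnorm(80)))
    expect_lte(nrow(mi), 80)
    expect_true(all(diff(mi$size_bp) > 0))
  }
})

test_that("cross-run alignment interpolates on the union grid without extrapolating", {
  one <- merge_traces(make_trace("a", c(500, 19900, 20100), c(1, 4, 8)))
  al1 <- align_runs(one)
  expect_equal(al1$size_bp, one$size_bp)
  expect_false(any(al1$interpolated))

  two <- dplyr::bind_rows(
    merge_traces(make_trace("a", c(500, 19900, 20100), c(1, 4, 8), run_id = "r1")),
    merge_traces(make_trace("b", c(500, 20000, 30000), c(2, 6, 3), run_id = "r2"))
  )
  al <- align_runs(two)
  a_at_20k <- al[al$sample_id == "a" & al$size_bp == 20000, ]
  expect_equal(a_at_20k$rfu, (4 + 8) / 2)   # midpoint of 19,900 and 20,100
  expect_true(a_at_20k$interpolated)
  a_at_30k <- al[al$sample_id == "a" & al$size_bp == 30000, ]
  expect_true(is.na(a_at_30k$rfu))          # outside a's observed range

  same_grid <- dplyr::bind_rows(
    merge_traces(make_trace("a", c(500, 1010, 20000), c(1, 2, 3), run_id = "r1")),
    merge_traces(make_trace("b", c(500, 1010, 20000), c(4, 5, 6), run_id = "r2"))
  )
  expect_false(any(align_runs(same_grid)$interpolated))

  short <- dplyr::bind_rows(one, merge_traces(make_trace("c", 500, 3)))
  expect_message(align_runs(short), "excluded 1")
})

test_that("group summaries: degenerate CI at zero variance, two-point t-interval oracle", {
  sizes <- c(300, 1010, 25000)
  traces <- dplyr::bind_rows(
    make_trace("s1", sizes, c(1, 2, 3)),
    make_trace("s2", sizes, c(1, 2, 3)),
    make_trace("s3", sizes, c(1, 2, 3))
  )
  design <- make_design(c("s1", "s2", "s3"), fish = c("fish1", "fish2", "fish3"))
  sm <- summarize_group(align_runs(merge_traces(traces)), design,
                        group_by = "solution")
  expect_equal(sm$ci_low, sm$mean_rfu)
  expect_equal(sm$ci_high, sm$mean_rfu)
  expect_equal(unique(sm$n_samples), 3)

  v <- 5; d <- 0.7
  two <- dplyr::bind_rows(
    make_trace("s1", sizes, rep(v + d, 3)),
    make_trace("s2", sizes, rep(v - d, 3))
  )
  d2 <- make_design(c("s1", "s2"), fish = c("fish1", "fish2"))
  sm2 <- summarize_group(align_runs(merge_traces(two)), d2, group_by = "solution")
  # closed-form two-point 95% t-interval: half-width qt(.975, 1) * sd/sqrt(2)
  # with sd = d*sqrt(2), i.e. exactly qt(.975, 1) * d
  expect_equal(sm2$ci_high - sm2$mean_rfu, rep(qt(0.975, 1) * d, 3))
  expect_equal(sm2$mean_rfu, rep(v, 3))
  # normal-quantile option gives the narrower band
  sm2n <- summarize_group(align_runs(merge_traces(two)), d2,
                          group_by = "solution", ci = "normal")
  expect_true(all(sm2n$ci_high < sm2$ci_high))
})

test_that("solution-level pooling of the default design gives n = 20 per group", {
  sim <- simulate_experiment(small_config())
  aligned <- align_runs(merge_traces(sim$traces))
  sm <- summarize_group(aligned, sim$design, group_by = "solution")
  groups <- dplyr::distinct(sm, solution, time_days, n_samples)
  expect_equal(nrow(groups), 10)   # 2 solutions x 5 time points
  expect_true(all(groups$n_samples == 20))
  expect_true(all(sm$ci_low <= sm$mean_rfu + 1e-12 &
                    sm$mean_rfu <= sm$ci_high + 1e-12))
})

test_that("CI half-width shrinks as group size grows at fixed point SD", {
  sizes <- c(300, 1010, 25000)
  mk <- function(n) {
    traces <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_trace(paste0("s", i), sizes, c(-1, 1, 0)[(i %% 3) + 1] + c(5, 5, 5))
    }))
    design <- make_design(paste0("s", seq_len(n)), fish = paste0("fish", seq_len(n)))
    sm <- summarize_group(align_runs(merge_traces(traces)), design,
                          group_by = "solution")
    mean(sm$ci_high - sm$mean_rfu)
  }
  expect_lt(mk(30), mk(6))
})
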