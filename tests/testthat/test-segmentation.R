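make_recording <- function(total_s, rr_ms = 1000) {
  rr_series(rep(rr_ms, ceiling(total_s * 1000 / rr_ms)))
}

test_that("recordings cut into half-open 5-min windows, partial tail dropped", {
  rr <- rr_series(rep(1000, 1800))           # exactly 1800 s
  expect_length(make_segments(rr), 6L)
  rr2 <- rr_series(rep(1000, 1799))          # 1799 s
  expect_length(make_segments(rr2), 5L)
  short <- rr_series(rep(1000, 200))
  expect_error(make_segments(short), "shorter")
})

test_that("a beat with onset 299.9 s belongs to segment 0", {
  rr <- rr_series(c(rep(999.667, 300), rep(1000, 301)))
  segs <- make_segments(rr)
  s0 <- segs[[1]]
  last_onset <- s0$rr$t_cum[length(s0$rr$intervals)]
  expect_lt(last_onset, 300)
  expect_gt(last_onset, 299.8)
  expect_equal(segs[[2]]$rr$t_cum[1] >= 300, TRUE)
})

test_that("stage fractions are overlap shares rounded half-up to one decimal", {
  hyp <- hypnogram(c("W", "N1", "N2", "N3"),
                   c(0, 120, 300, 400), c(120, 300, 400, 900))
  # segment fully inside one stage
  fr <- stage_fractions(450, 750, hyp)
  expect_equal(unname(fr["N3"]), 1.0)
  expect_equal(sum(fr), 1.0)
  # 120 s W then 180 s N1
  fr <- stage_fractions(0, 300, hyp)
  expect_equal(unname(fr[c("W", "N1")]), c(0.4, 0.6))
  # 100 s N2 then 200 s N3: thirds round to 0.3 / 0.7
  fr <- stage_fractions(300, 600, hyp)
  expect_equal(unname(fr[c("N2", "N3")]), c(0.3, 0.7))
  expect_error(stage_fractions(600, 1000, hyp), "span")
})

test_that("unrounded overlaps sum exactly to the window length (property)", {
  set.seed(7)
  for (rep in 1:10) {
    cuts <- sort(c(0, sample(1:3599, 8), 3600))
    hyp <- hypnogram(sample(sleep_stages(), 9, replace = TRUE),
                     cuts[-10], cuts[-1])
    for (k in 0:11) {
      fr <- stage_fractions(k * 300, (k + 1) * 300, hyp, round = FALSE)
      expect_equal(sum(fr) * 300, 300)
    }
  }
})

test_that("certain-stage threshold is inclusive at 0.7", {
  fr <- c(W = 0, N1 = 0, N2 = 0.3, N3 = 0.7, R = 0)
  expect_equal(certain_stage(fr),
               c(W = 0L, N1 = 0L, N2 = 0L, N3 = 1L, R = 0L))
  fr69 <- c(W = 0, N1 = 0, N2 = 0.69, N3 = 0.31, R = 0)
  expect_true(all(certain_stage(fr69) == 0L))
  expect_equal(sum(certain_stage(c(W = 1, N1 = 0, N2 = 0, N3 = 0, R = 0))), 1L)
  expect_true(all(certain_stage(c(W = 0, N1 = 0.6, N2 = 0.4, N3 = 0,
                                  R = 0)) == 0L))
})

test_that("certain_stage is monotone in each fraction", {
  set.seed(3)
  for (rep in 1:50) {
    fr <- round(stats::runif(5), 1)
    names(fr) <- sleep_stages()
    base <- certain_stage(fr)
    s <- sample(sleep_stages(), 1)
    fr2 <- fr
    fr2[s] <- min(1, fr[s] + 0.1)
    raised <- certain_stage(fr2)
    expect_gte(raised[s], base[s])
  }
})

frac_mat <- function(...) {
  m <- cbind(...)
  full <- matrix(0, nrow(m), 5, dimnames = list(NULL, sleep_stages()))
  full[, colnames(m)] <- m
  full
}

test_that("transition rule A fires while the ending stage grows under 0.6", {
  fr <- frac_mat(W = c(1.0, 0.6, 0.0), N1 = c(0.0, 0.4, 1.0))
  tr <- mark_transitions(fr)
  # rule A at t = 1 (0.4 <= 0.6 and 0.4 >= 0); rule B also fires at t = 0
  # because W is pure there and N1 appears at <= 0.6 in the next segment
  expect_equal(unname(tr[, "trans_W_N1"]), c(1L, 1L, 0L))
  expect_true(all(tr[, colnames(tr) != "trans_W_N1"] == 0L))
})

test_that("transition rule B fires when the change sits on the boundary", {
  fr <- frac_mat(N2 = c(1.0, 0.4), R = c(0.0, 0.5))
  tr <- mark_transitions(fr)
  expect_equal(unname(tr[1, "trans_N2_R"]), 1L)
  # rule A independently fires at t = 1 (both present, 0.5 <= 0.6, rising)
  expect_equal(unname(tr[2, "trans_N2_R"]), 1L)
})

test_that("rule A requires a non-receding ending stage", {
  # N1 fraction decreasing from 0.5 to 0.3: segment 1 must not re-mark
  fr <- frac_mat(W = c(0.5, 0.7), N1 = c(0.5, 0.3))
  tr <- mark_transitions(fr)
  expect_equal(unname(tr[, "trans_W_N1"]), c(1L, 0L))
})

test_that("ending fractions above 0.6 never mark a transition", {
  fr <- frac_mat(W = c(0.3, 0.3), N1 = c(0.7, 0.7))
  expect_true(all(mark_transitions(fr)[, "trans_W_N1"] == 0L))
})

test_that("single-stage recordings carry no transitions", {
  fr <- frac_mat(N2 = rep(1.0, 6))
  expect_true(all(mark_transitions(fr) == 0L))
})

test_that("a pure stage change on a window boundary fires no rule A in pure windows", {
  fr <- frac_mat(N2 = c(1, 1, 0, 0), N3 = c(0, 0, 1, 1))
  tr <- mark_transitions(fr)
  # rule B marks the last pure N2 window; no rule-A marks in pure windows
  expect_equal(unname(tr[, "trans_N2_N3"]), c(0L, 0L, 0L, 0L))
})

test_that("unknown transition pairs are rejected", {
  fr <- frac_mat(N2 = c(1, 0), N3 = c(0, 1))
  expect_error(mark_transitions(fr, pairs = matrix(c("N2", "Q"), 1)),
               "unknown")
})
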