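test_that("delta classification follows sign of the change", {
  expect_equal(classify_deltas(c(800, 810, 810, 790)),
               c("dec", "neutral", "acc"))
  expect_true(all(classify_deltas(seq(700, 900, by = 10)) == "dec"))
  x <- c(800, 825, 825, 790, 800)
  expect_equal(classify_deltas(rev(x)),
               rev(ifelse(classify_deltas(x) == "dec", "acc",
                          ifelse(classify_deltas(x) == "acc", "dec",
                                 "neutral"))))
})

test_that("variance decomposition is exact on closed-form cases", {
  vd <- variance_decomposition(rep(777, 20))
  expect_true(all(unlist(vd) == 0))

  x <- c(rep(c(800, 820), 50), 800)   # 100 deltas: 50 dec, 50 acc
  vd <- variance_decomposition(x)
  expect_equal(vd$sd1d^2, sd1(x)^2 / 2, tolerance = 1e-12)
  expect_equal(vd$sd1a^2, sd1(x)^2 / 2, tolerance = 1e-12)
})

test_that("partition identities hold to 1e-9 relative on random series", {
  set.seed(2024)
  for (rep in 1:50) {
    x <- random_rr(sample(10:300, 1))
    x[sample(length(x), 3)] <- x[1]      # force some ties
    vd <- variance_decomposition(x)
    s1 <- sd1(x)^2
    s2 <- sd2(x)^2
    expect_equal(vd$sd1d^2 + vd$sd1a^2, s1, tolerance = 1e-9)
    expect_equal(vd$sd2d^2 + vd$sd2a^2, s2, tolerance = 1e-9)
    expect_equal(vd$sdnnd^2 + vd$sdnna^2, (s1 + s2) / 2, tolerance = 1e-9)
  }
})

test_that("runs partition matches the hand-traced example", {
  d <- runs_partition(c(800, 810, 820, 800, 790, 790))
  expect_equal(unname(d$dr_counts["2"]), 1L)
  expect_equal(unname(d$ar_counts["2"]), 1L)
  expect_equal(unname(d$neutral_counts["1"]), 1L)
  expect_equal(d$dr_max, 2L)
  expect_equal(d$ar_max, 2L)
  expect_equal(run_count(d, "dec", 4), 0L)
})

test_that("a strictly increasing series is one long deceleration run", {
  n <- 25
  d <- runs_partition(seq(700, by = 5, length.out = n))
  expect_equal(unname(d$dr_counts[as.character(n - 1)]), 1L)
  expect_equal(d$ar_max, 0L)
  expect_equal(d$dr_max, n - 1L)
})

test_that("run lengths conserve the number of deltas (property)", {
  set.seed(55)
  for (rep in 1:30) {
    x <- round(random_rr(sample(5:400, 1)))
    d <- runs_partition(x)
    tot <- function(cnt) sum(as.integer(names(cnt)) * cnt)
    expect_equal(tot(d$dr_counts) + tot(d$ar_counts) +
                   tot(d$neutral_counts), length(x) - 1L)
  }
})

test_that("runs entropy matches closed forms", {
  single <- runs_partition(c(800, 810))          # one DR1 only
  e <- runs_entropy(single)
  expect_equal(e$hdr, 0)
  expect_equal(e$har, 0)
  expect_equal(e$h_total, 0)

  both <- runs_partition(c(800, 810, 800))       # one DR1, one AR1
  e <- runs_entropy(both)
  expect_equal(e$hdr, 0.5)
  expect_equal(e$har, 0.5)
  expect_equal(e$h_total, 1)
  # natural-log base scales everything by log(2)
  en <- runs_entropy(both, base = exp(1))
  expect_equal(en$h_total, log(2))
})

test_that("merging two run-length bins never raises hdr (concavity)", {
  set.seed(12)
  for (rep in 1:20) {
    x <- round(random_rr(200))
    d <- runs_partition(x)
    if (length(d$dr_counts) < 2L) next
    e0 <- runs_entropy(d)$hdr
    merged <- d
    k <- names(merged$dr_counts)[1:2]
    merged$dr_counts <- c(sum(merged$dr_counts[k]),
                          merged$dr_counts[-(1:2)])
    names(merged$dr_counts)[1] <- k[1]
    expect_lte(runs_entropy(merged)$hdr, e0 + 1e-12)
  }
})

test_that("threshold counts use strict +/-30 ms and partition pnn30", {
  tc <- threshold_counts(c(800, 840, 800))
  expect_equal(tc$pnn30dec, 50)
  expect_equal(tc$pnn30acc, 50)
  tc <- threshold_counts(c(800, 831, 800))
  expect_equal(tc$pnn30dec, 50)
  expect_equal(tc$pnn30acc, 50)
  tc <- threshold_counts(c(800, 830, 800))
  expect_equal(tc$pnn30dec, 0)
  expect_equal(tc$pnn30acc, 0)

  set.seed(31)
  for (rep in 1:25) {
    x <- round(random_rr(sample(5:300, 1)))
    tc <- threshold_counts(x)
    expect_equal(tc$pnn30dec + tc$pnn30acc, pnn30(x))
  }
})

test_that("time reversal swaps every deceleration/acceleration quantity", {
  set.seed(404)
  for (rep in 1:25) {
    x <- round(random_rr(sample(10:300, 1)), 1)
    rx <- rev(x)
    vd <- variance_decomposition(x)
    vr <- variance_decomposition(rx)
    expect_equal(vd$sd1d, vr$sd1a, tolerance = 1e-12)
    expect_equal(vd$sd1a, vr$sd1d, tolerance = 1e-12)
    expect_equal(vd$sd2d, vr$sd2a, tolerance = 1e-12)
    expect_equal(vd$sdnnd, vr$sdnna, tolerance = 1e-12)

    d <- runs_partition(x)
    dr <- runs_partition(rx)
    expect_equal(d$dr_counts, dr$ar_counts)
    expect_equal(d$ar_counts, dr$dr_counts)
    expect_equal(d$dr_max, dr$ar_max)
    expect_equal(d$ar_max, dr$dr_max)

    e <- runs_entropy(d)
    er <- runs_entropy(dr)
    expect_equal(e$hdr, er$har, tolerance = 1e-12)
    expect_equal(e$har, er$hdr, tolerance = 1e-12)

    tc <- threshold_counts(x)
    tr <- threshold_counts(rx)
    expect_equal(tc$pnn30dec, tr$pnn30acc)
    expect_equal(tc$pnn30acc, tr$pnn30dec)
  }
})

test_that("asymmetry features are invariant to adding a constant", {
  set.seed(66)
  x <- round(random_rr(150))
  y <- x + 200
  expect_equal(variance_decomposition(x), variance_decomposition(y),
               tolerance = 1e-9)
  expect_equal(runs_partition(x)[1:5], runs_partition(y)[1:5])
  expect_equal(threshold_counts(x), threshold_counts(y))
})
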