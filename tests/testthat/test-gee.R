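test_that("independence GEE with singleton clusters equals the logistic MLE", {
  set.seed(1)
  n <- 200
  d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                  x1 = rnorm(n), x2 = rnorm(n))
  p <- plogis(-0.5 + 1.2 * d$x1 - 0.8 * d$x2)
  d$y <- rbinom(n, 1, p)
  fit <- fit_gee(d, "y", c("x1", "x2"), "subject_id",
                 corstr = "independence")
  ref <- glm(y ~ x1 + x2, binomial, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("zero-variance covariates are excluded with NA coefficients", {
  set.seed(2)
  d <- simulate_clustered(10, 30, beta0 = -0.5, beta_x = 1)
  d$flat <- 0
  fit <- fit_gee(d, "y", c("x", "flat"), "subject_id")
  expect_equal(fit$excluded, "flat")
  expect_true(is.na(fit$coef_full["flat"]))
  ref <- fit_gee(d, "y", "x", "subject_id")
  expect_equal(fit$coefficients, ref$coefficients, tolerance = 1e-10)
})

test_that("an exchangeable GEE recovers a known effect on clustered data", {
  set.seed(3)
  d <- simulate_clustered(30, 100, beta0 = -2, beta_x = 1.0, sigma_u = 0.7)
  fit <- fit_gee(d, "y", "x", "subject_id", corstr = "exchangeable")
  expect_lt(abs(fit$coefficients["x"] - 1.0), 0.2)
  expect_true(fit$converged)
  expect_gt(fit$alpha, 0)
  expect_true(all(fit$se > 0))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
})

test_that("estimated alpha shrinks when cluster structure is destroyed", {
  set.seed(4)
  d <- simulate_clustered(25, 60, beta0 = -1, beta_x = 0.5, sigma_u = 1.0)
  fit <- fit_gee(d, "y", "x", "subject_id", corstr = "exchangeable")
  shuffled <- d
  shuffled$subject_id <- sample(shuffled$subject_id)
  fit_sh <- fit_gee(shuffled, "y", "x", "subject_id",
                    corstr = "exchangeable")
  expect_gt(fit$alpha, fit_sh$alpha)
})

test_that("coefficients rescale under affine covariate rescaling", {
  set.seed(5)
  d <- simulate_clustered(15, 40, beta0 = -1, beta_x = 0.8)
  f1 <- fit_gee(d, "y", "x", "subject_id")
  d$x <- d$x * 10
  f2 <- fit_gee(d, "y", "x", "subject_id")
  expect_equal(unname(f2$coefficients["x"]) * 10,
               unname(f1$coefficients["x"]), tolerance = 1e-4)
})

test_that("degenerate responses and missing columns raise errors", {
  d <- data.frame(subject_id = rep(c("a", "b"), 10), x = rnorm(20),
                  y = rep(1, 20))
  expect_error(fit_gee(d, "y", "x", "subject_id"), "one class")
  d$y[1] <- 0
  expect_error(fit_gee(d, "y", "nope", "subject_id"), "not in data")
})

test_that("prediction equals the hand-computed logistic formula", {
  set.seed(6)
  d <- simulate_clustered(12, 40, beta0 = -1, beta_x = 1)
  fit <- fit_gee(d, "y", "x", "subject_id")
  nd <- data.frame(x = c(-1.3, 0, 2.2))
  expect_equal(predict(fit, nd),
               plogis(fit$coefficients[1] + fit$coefficients[2] * nd$x),
               ignore_attr = TRUE)
  expect_error(predict(fit, data.frame(z = 1)), "lacks covariates")
})

test_that("backward selection retains a strong effect and drops pure noise", {
  set.seed(7)
  d <- simulate_clustered(20, 80, beta0 = -1, beta_x = 1.2, sigma_u = 0.4)
  for (k in 1:4) d[[paste0("noise", k)]] <- rnorm(nrow(d))
  sel <- backward_select(d, "y", c("x", paste0("noise", 1:4)),
                         "subject_id")
  expect_true("x" %in% sel$covariates)
  expect_true(all(diff(sel$selection_trace$criterion) <= 1e-9))
})

test_that("under an intercept-only truth most noise covariates are dropped", {
  set.seed(8)
  keeps <- integer(10)
  for (s in 1:10) {
    set.seed(100 + s)
    d <- simulate_clustered(15, 40, beta0 = -0.7, beta_x = 0, sigma_u = 0.3)
    for (k in 1:4) d[[paste0("noise", k)]] <- rnorm(nrow(d))
    sel <- backward_select(d, "y", c("x", paste0("noise", 1:4)),
                           "subject_id", corstr = "independence")
    keeps[s] <- length(sel$covariates)
  }
  expect_gte(mean(keeps <= 1), 0.8)
})

test_that("stratified split keeps subjects whole and near the target share", {
  set.seed(9)
  coh_tab <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:10), each = 20),
    certain_W = rbinom(200, 1, 0.3), certain_N2 = rbinom(200, 1, 0.4))
  sp <- stratified_subject_split(coh_tab, train_frac = 0.7, n_strata = 2,
                                 seed = 5)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$test_subjects),
                  unique(coh_tab$subject_id))
  expect_length(sp$train_subjects, 7)
  sp2 <- stratified_subject_split(coh_tab, train_frac = 0.7, n_strata = 2,
                                  seed = 5)
  expect_identical(sp, sp2)  # same seed, same plan
  expect_error(stratified_subject_split(coh_tab[1:20, ]), "3 subjects")
})

test_that("the achieved training fraction lands near 0.71 on a 31-subject cohort", {
  set.seed(10)
  coh_tab <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:31), each = 30),
    certain_W = rbinom(930, 1, 0.25), certain_N2 = rbinom(930, 1, 0.35),
    certain_N3 = rbinom(930, 1, 0.15))
  fracs <- vapply(1:20, function(s) {
    stratified_subject_split(coh_tab, 0.7, 4, seed = s)$achieved_train_fraction
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.71), 0.05)
})
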