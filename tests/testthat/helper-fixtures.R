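# Small generators used across the suite. All randomness is seeded at the
# call site.

random_rr <- function(n, mean = 900, sd = 40) {
  pmin(pmax(stats::rnorm(n, mean, sd), 300), 2500)
}

# naive O(n^2) sample-entropy oracle: literal double loop over template
# pairs with Chebyshev distance, self-matches excluded
sampen_naive <- function(x, m, tol) {
  n <- length(x)
  last <- n - m                       # same start range for m and m + 1
  count <- function(len) {
    tot <- 0
    for (i in seq_len(last - 1)) {
      for (j in seq(i + 1, last)) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= tol) {
          tot <- tot + 1
        }
      }
    }
    tot
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# brute-force AUC over all positive/negative pairs, ties at 1/2
auc_naive <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# clustered logistic data with known coefficients and normal random
# intercepts per cluster
simulate_clustered <- function(n_clusters, n_per, beta0, beta_x,
                               sigma_u = 0.8) {
  id <- rep(sprintf("C%02d", seq_len(n_clusters)), each = n_per)
  u <- rep(stats::rnorm(n_clusters, 0, sigma_u), each = n_per)
  x <- stats::rnorm(n_clusters * n_per)
  p <- stats::plogis(beta0 + beta_x * x + u)
  data.frame(subject_id = id, x = x,
             y = stats::rbinom(length(p), 1, p))
}

# tiny two-subject cohort for pipeline tests
tiny_cohort <- function(n_subjects = 4, hours = 1, seed = 11, ...) {
  cfg <- cohort_config(n_subjects = n_subjects, recording_hours = hours, ...)
  generate_cohort(cfg, seed = seed)
}
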