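# Independent rating-scale model machinery for oracle tests: written from the
# closed-form category probabilities, not via the package's internals.
rsm_prob_oracle <- function(theta, delta, tau) {
  # returns length-3 probability vector for one person x one item
  num <- c(1,
           exp(theta - delta - tau[1]),
           exp(2 * (theta - delta) - tau[1] - tau[2]))
  num / sum(num)
}

rsm_sample_oracle <- function(theta, delta, tau, seed) {
  set.seed(seed)
  n <- length(theta); I <- length(delta)
  X <- matrix(0L, n, I)
  for (p in seq_len(n)) {
    for (i in seq_len(I)) {
      pr <- rsm_prob_oracle(theta[p], delta[i], tau)
      X[p, i] <- sample(0:2, 1L, prob = pr)
    }
  }
  colnames(X) <- sprintf("item%02d", seq_len(I))
  X
}

rsm_expected_score_oracle <- function(theta, delta, tau) {
  sum(vapply(delta, function(d) {
    pr <- rsm_prob_oracle(theta, d, tau)
    pr[2] + 2 * pr[3]
  }, numeric(1)))
}

random_field <- function(patient = "p1", eye = "OD", pattern = "10-2",
                         mean_td = -15, sd_td = 5) {
  g <- vf_grid(pattern, switch(eye, OD = "right", OS = "left"))
  monocular_field(patient, eye, pattern, rnorm(nrow(g), mean_td, sd_td))
}

# a constant-free quiet cohort config for fast unit tests
quiet_config <- function(n = 60, seed = 1, ...) {
  cohort_config(n = n, seed = seed, ...)
}
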