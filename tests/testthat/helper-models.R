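# Shared fixtures: the weak-coupling study model and small helpers.

study_model <- function(eps = 0, delta = 10^(-1.4), gamma = 0.25) {
  sb_model(lam = 12, eps = eps, delta = delta, omega = 0.25, gamma = gamma)
}

# relative rate deviation and its stderr from a plateau fit
rate_vs_marcus <- function(rate, m) {
  kmt <- marcus_rate(m)$k
  list(ratio = rate$k / kmt, rel_se = rate$stderr / kmt)
}

expect_within_se <- function(value, target, se, n_se = 3) {
  expect_lt(abs(value - target), n_se * se)
}
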