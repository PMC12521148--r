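# Shared helpers for the test suite.

# Effectiveness table in the printed 2-decimal dialect (the form the study's
# cost-effectiveness cells were computed from).
printed_effectiveness <- function() {
  dplyr::mutate(asthma_effectiveness(),
                rate_percent = round(rate_percent, 2))
}

# Expand threshold exceedance counts into one duration per patient: each
# patient gets the largest threshold they reached (0 for none). Preserves
# the threshold-achievement counts exactly.
durations_from_counts <- function(n, counts, thresholds = c(3, 6, 12, 24)) {
  k <- length(thresholds)
  reached <- c(counts, 0)        # counts at t1..tk, then "beyond none"
  per_level <- counts - c(counts[-1], 0)  # exactly at each threshold
  rep(c(thresholds, 0), c(per_level, n - counts[1]))
}

# Strategy table built directly from numeric vectors, for small synthetic
# cases.
make_params <- function(label, costs, probs, utils = c(11.646, 13.806, 15.606),
                        basis = "ics", tol = 1e-9) {
  strategy_params(
    tibble::tibble(strategy = label, state = health_states(),
                   cost_cny = costs, probability = probs,
                   utility_qaly = utils),
    cost_basis = basis, prob_tol = tol
  )
}
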