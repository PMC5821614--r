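# Small in-code fixtures shared across tests. Unit tests run on deliberately
# tiny libraries and ensembles; statistical behaviour at realistic sizes is
# exercised in test-acceptance.R.

tiny_library <- function(n = 200, hit_rate = 0.2, effect_size = 2,
                         seed = 42, ...) {
  simulate_library(library_spec(
    n_compounds = n, hit_rate = hit_rate, n_features = 16,
    n_informative = 8, effect_size = effect_size, seed = seed, ...
  ))
}

# A p-value table with perfect class separation for the given truth.
perfect_pvals <- function(truth) {
  act <- truth == "active"
  data.frame(p_active = as.numeric(act), p_inactive = as.numeric(!act))
}

# Brute-force conformal p-value: explicit strict-lower count.
pval_oracle <- function(score, calibration) {
  vapply(score, function(s) sum(calibration < s), numeric(1)) /
    (length(calibration) + 1)
}
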