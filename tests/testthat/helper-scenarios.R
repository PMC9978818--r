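# Shared scenario builders: the reference mAb pair/trio mixed under the
# canonical BLI conditions (5 ug/ml total IgG ~ 33.3 nM, 300 s association,
# 600 s dissociation at 5 Hz).

binary_mixture <- function(seed = 1L, sigma = 0.005, t_assoc = 300,
                           share = c(0.25, 0.75)) {
  simulate_mixture_sensorgram(npna3_mabs()[c(1, 3), ], share,
                              sigma = sigma, t_assoc = t_assoc, seed = seed)
}

ternary_mixture <- function(seed = 1L, sigma = 0.005) {
  simulate_mixture_sensorgram(npna3_mabs(), rep(1 / 3, 3),
                              sigma = sigma, seed = seed)
}

# component shares of the simulated total at a given time into dissociation
truth_shares_at <- function(truth, t_dissoc_offset) {
  comp <- truth$sim$dissoc$components
  tt <- truth$sim$dissoc$times
  v <- vapply(seq_len(ncol(comp)), function(j)
    stats::approx(tt, comp[, j], xout = t_dissoc_offset)$y, numeric(1L))
  stats::setNames(v / sum(v), colnames(comp))
}
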