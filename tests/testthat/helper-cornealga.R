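# shared fixtures, built in code at test time

# small planted table used by several GA tests
tiny_planted <- function(seed = 1, n = 120, w = 6, k = 2, effect = 5) {
  planted_features(n_samples = n, n_channels = w, k_informative = k,
                   effect_size = effect, seed = seed)
}

# brute-force oracle: best fitness over all subsets of given size
brute_force_best <- function(table, size, estimator) {
  subsets <- utils::combn(ncol(ft_matrix(table)), size)
  max(apply(subsets, 2, evaluate_fitness, table = table,
            estimator = estimator))
}
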