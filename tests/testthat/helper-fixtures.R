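# Shared fixtures, built in code at test time.

fixture_3tip <- function() parse_newick("((A:1,B:1):1,C:2);")

fixture_4tip <- function() {
  parse_newick("((A:0.1,B:0.1):0.9,(C:0.2,D:0.2):0.8);")
}

# small mixed-tree fixture with its truth
fixture_mixed <- function(seed = 1L, k = 4L, n_j = 5L) {
  simulate_mixed_tree(k = k, lambda1 = 1, n_j = n_j, lambda2 = 200,
                      seed = seed)
}

# random coalescent tree with random size, for property sweeps
random_small_tree <- function(seed, n_min = 3L, n_max = 6L) {
  n <- n_min + (seed %% (n_max - n_min + 1L))
  simulate_null_tree(n, lambda2 = 1 + (seed %% 5), seed = seed)
}
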