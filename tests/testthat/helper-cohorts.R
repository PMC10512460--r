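# Small simulated cohorts shared across tests. All fixtures are generated
# in code under fixed seeds; nothing is read from disk.

# Cohort with strong bidirectional planted effects: easily separable.
separable_cohort <- function(seed = 1, n_nodes = 20, n_per = 20,
                             delta = 0.8) {
  plan <- effect_plan(n_nodes = n_nodes, increased_edges = 0:9,
                      decreased_edges = 10:19, delta = delta)
  generate_cohort(plan, n_per, n_per, seed = seed)
}

# Pure-noise cohort (no planted effects).
null_cohort <- function(seed = 1, n_nodes = 20, n_per = 15) {
  generate_cohort(effect_plan(n_nodes = n_nodes), n_per, n_per, seed = seed)
}

# A random symmetric zero-diagonal matrix.
random_symmetric <- function(n_nodes, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_nodes^2), n_nodes)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
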