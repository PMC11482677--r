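# Small fixtures built in code; heavier shared objects are memoised per
# session so several test files can reuse them.

tri_net <- function() {
  bipartite_network(matrix(c(
    1, 1, 1,
    1, 1, 0,
    1, 0, 0
  ), 3, byrow = TRUE))
}

# one plant connected to k animals
star_net <- function(k = 4) {
  bipartite_network(matrix(1, 1, k))
}

# single mutualistic pair (sigma ~ 0 makes the closed-form fixed point exact)
pair_net <- function() bipartite_network(matrix(1, 1, 1))

pair_params <- function(gamma0, sigma = 1e-5, ...) {
  sample_params(pair_net(), gamma0 = gamma0, sigma = sigma,
                alpha = diag(2), ...)
}

.fixture_cache_env <- new.env(parent = emptyenv())
fixture_cache <- function(name, expr) {
  if (!exists(name, .fixture_cache_env)) {
    assign(name, force(expr), .fixture_cache_env)
  }
  get(name, .fixture_cache_env)
}

# 17-species nested fixture used by the kernel-contrast checks
kernel_fixture <- function() {
  fixture_cache("kernel_net", generate_nested_network(
    8, 9, 0.29, nodf = 0.30, tol = 0.03, seed = 17
  ))
}

# ~50-species nested fixture emulating the mid-size studied networks
revival_fixture <- function() {
  fixture_cache("revival_net", generate_nested_network(
    25, 25, 0.17, nodf = 0.35, seed = 42
  ))
}

# 30-species ensemble: fixed size and connectance, NODF spanning 0.3 to the
# most nested attainable matrix
ensemble_fixture <- function() {
  fixture_cache("ensemble", generate_network_ensemble(
    n = 10, s_plant = 15, s_animal = 15, connectance = 0.42,
    nodf_range = c(0.3, 1), seeds = 1:10
  ))
}
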