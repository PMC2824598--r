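# Shared fixtures: networks and parameter sets are cheap to build, so each
# helper constructs fresh objects.

simple_net <- function(...) build_network("simple", ...)
full_net <- function() build_network("full")

# Independent flux-by-flux accumulation over the reaction list, used as the
# brute-force oracle for the vectorized right-hand side.
brute_force_rhs <- function(state, k, network) {
  f <- numeric(network$n_species)
  for (r in network$reactions) {
    flux <- k[[r$sym]] * prod(state[r$re])
    for (i in r$re) f[i] <- f[i] - flux
    for (i in r$pr) f[i] <- f[i] + flux
  }
  setNames(f, paste0("x", seq_len(network$n_species)))
}

# Finite-difference Jacobian oracle.
fd_jacobian <- function(state, k, network, h = 1e-7) {
  n <- network$n_species
  J <- matrix(0, n, n)
  f0 <- network_rhs(state, k, network)
  for (j in seq_len(n)) {
    sp <- state; sp[j] <- sp[j] + h
    J[, j] <- (network_rhs(sp, k, network) - f0) / h
  }
  J
}

# All-zero rate vector with selected overrides, for constructed sub-systems.
zero_rates <- function(...) {
  k <- setNames(numeric(38), paste0("k", 1:38))
  ov <- c(...)
  k[names(ov)] <- ov
  k
}
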