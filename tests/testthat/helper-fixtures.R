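# shared fixtures, built in code

embryo_densities <- c(2, 4, 6, 8, 10, 15, 20, 40, 70)
larvae_densities <- c(1, 2, 3, 5, 8, 10, 15)

embryo_trials <- function(a = 0.85, h = 0.258, seed = 101, replicates = 5,
                          ...) {
  generate_trials(sim_config(a = a, h = h, T = 1,
                             densities = embryo_densities,
                             replicates = replicates, seed = seed, ...))
}

larvae_trials <- function(a = 0.392, h = 0.988, seed = 202, replicates = 11,
                          ...) {
  generate_trials(sim_config(a = a, h = h, T = 2,
                             densities = larvae_densities,
                             replicates = replicates, seed = seed, ...))
}

# root of the implicit depletion equation N_e = N_0 (1 - exp(a (N_e h - T)))
# on [0, N_0], found by bisection -- independent of the Lambert W route.
# (plain fixed-point iteration of this map is not a contraction at
# published-scale a*h*N_0 and can run off to a spurious negative root)
rogers_implicit_root <- function(a, h, T, N0) {
  g <- function(ne) ne - N0 * (1 - exp(a * (ne * h - T)))
  uniroot(g, c(0, N0), tol = 1e-13)$root
}
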