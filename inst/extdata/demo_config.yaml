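# Demonstration run: three simulated predator size groups feeding on
# amphibian larvae over 2-day depletion trials, plus simulated quadrat
# surveys, compared through to Relative Impact Potential.
seed: 42
alpha: 0.05
n_boot: 200        # curve bands (use 2000 for production runs)
n_boot_fr: 30      # max-feeding-rate mean +/- SE
n_draws: 20000     # RIP Monte Carlo draws (use 100000 for production runs)
feeding_rate: per_day
trials:
  simulate:
    - {group: "large invader", prey: "larva", a: 0.392, h: 0.988, T: 2,
       densities: [1, 2, 3, 5, 8, 10, 15], replicates: 11}
    - {group: "intermediate invader", prey: "larva", a: 0.597, h: 2.803, T: 2,
       densities: [1, 2, 3, 5, 8, 10, 15], replicates: 11}
    - {group: "native", prey: "larva", a: 0.30, h: 4.5, T: 2,
       densities: [1, 2, 3, 5, 8, 10, 15], replicates: 11}
quadrats:
  simulate:
    - {group: "large invader", mean_density: 14.76, dispersion: 4, n_sites: 12}
    - {group: "intermediate invader", mean_density: 83.28, dispersion: 4,
       n_sites: 12}
    - {group: "native", mean_density: 17.38, dispersion: 4, n_sites: 12}
compare:
  - ["large invader", "intermediate invader"]
  - ["large invader", "native"]
  - ["intermediate invader", "native"]
rip:
  - ["large invader", "native"]
  - ["intermediate invader", "native"]
  - ["intermediate invader", "large invader"]
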