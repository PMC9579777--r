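# Example simulation configuration for `abilitygame evolve --config ...`
# Flat key = value format; keys mirror sim_config() plus the cost exponent p.

mode = "sexual"        # "sexual" (infinitesimal model) or "asexual"
p = 1.5                # cost exponent of K(a, e) = (2 - a) e^p, must be > 1
n_individuals = 500    # population size (even; individuals pair)
n_generations = 2000   # generations to simulate
initial_ability = 1.0  # founding trait value, in [0, 1]
segregation_sd = 0.04  # infinitesimal-model segregation sd (sexual mode)
mutation_prob = 0.02   # per-offspring mutation probability (asexual mode)
mutation_sd = 0.08     # mutation effect sd (asexual mode)
selection_intensity = 20  # exponential payoff weighting, per payoff unit
record_every = 50      # quantile-series thinning interval
seed = 1               # RNG seed; runs are bit-reproducible
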