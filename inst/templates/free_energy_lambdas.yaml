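# Alchemical decoupling schedule template for self-solvation free energies
# (documentation only; the estimator runs in the external MD engine).
# LJ and electrostatic contributions are decoupled separately; soft-core
# parameters avoid instabilities near the noninteracting state.
lj_lambdas: [0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
             0.6, 0.7, 0.8, 0.9, 1]
coulomb_lambdas: [0, 0.2, 0.4, 0.6, 0.8, 1]
soft_core: {sc_power: 1, sc_sigma: 0.3, sc_alpha_lj: 0.5, sc_alpha_coulomb: 0}
run_length_ns:
  lj_per_lambda: 10
  coulomb_per_lambda: {alkylsilane: 5, alkoxysilane: 10, silanol: 20}
integrator: stochastic dynamics (leapfrog)
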