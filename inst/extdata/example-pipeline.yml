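# Example twinace pipeline configuration: simulate a bivariate AE cohort,
# run twin correlations, the univariate model menu, the multivariate fit,
# the clustered association model and the ordered Cholesky decomposition.
seed: 1
output_dir: twinace-report
cohort:
  simulate:
    n_mz: 418
    n_dz: 188
    n_singles: 600
    spec:
      a2: [0.5, 0.4]
      rA: [1.0, 0.85, 0.85, 1.0]
      rE: [1.0, 0.75, 0.75, 1.0]
      trait_names: [MM-T, MM-E]
stages: [correlations, assumptions, univariate, multivariate, association, decompose]
models: [ACE, AE, CE, E]
n_starts: 3
association:
  response: [MM-T]
  predictors: [score_MM-E]
  threshold: 0.01
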