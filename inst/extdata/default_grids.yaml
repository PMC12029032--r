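# Default hyperparameter search spaces for the grid-search stage.
# Schema: family -> parameter -> list of candidate values.
# Grids are deliberately compact; edit this file (or pass `grids` in the run
# config) to widen a search. Parameter names must be valid for the family
# (see ?classifier_spec).
NB:
  laplace: [0.0, 0.5, 1.0]
GLM:
  lambda: [0.001, 0.01, 0.05, 0.1, 1.0]
LR:
  lambda: [0.001, 0.01, 0.05, 0.1, 1.0]
FLM:
  cost: [0.01, 0.1, 1.0, 10.0]
DL:
  size: [3, 5, 8]
  decay: [0.001, 0.01, 0.1]
DT:
  maxdepth: [2, 4, 8]
  cp: [0.001, 0.01]
RF:
  num_trees: [300, 500]
  mtry_frac: [0.1, 0.33]
GBT:
  nrounds: [50, 100]
  max_depth: [2, 3]
  eta: [0.1, 0.3]
SVM:
  cost: [0.1, 1.0, 10.0]
  gamma_frac: [0.1, 1.0, 10.0]
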