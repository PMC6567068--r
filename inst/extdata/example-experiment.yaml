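# Desk-scale seawater experiment: simulate the 11-class library on the
# 16 mV grid, train and evaluate the two hybrid models.
scheme: 11-SW
seed: 7
preset: desk
models:
  - lstm_fcn
  - alstm_fcn
library:
  scale: 0.2
  grid_step: 0.016
split:
  n_repeats: 5
output_dir: cswv-out
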