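# Example configuration: simplified OLM-PYR feedback circuit at the
# calibrated Schaffer-collateral input level. Unset keys take defaults
# (variant FM, scil 140, duration 6300 ms, discard 2000 ms, dt 0.05 ms,
# seed 1, n_replicates 2). Load with load_config().
variant: SM
scil: 180
seed: 1
n_replicates: 2
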