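# Turning-point experiment, losing arm: identical to the recovering arm in
# every respect except the oxygen delivered per endothelial cell per step
# (angio.s_O2).  Vessels are recruited but deliver too little oxygen: the
# tumor passes its turning point and dies out completely.
dims: [34, 34, 34]
n_steps: 500
seed: 1
snapshot_every: 10
vessels_enabled: true
angio:
  s_O2: 0.0
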