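# Turning-point experiment, winning arm: identical to the dying arm in
# every respect except the oxygen delivered per endothelial cell per step
# (angio.s_O2).  The recruited vessels deliver enough oxygen to rescue the
# starving rim: the tumor recovers and resumes growth.
dims: [34, 34, 34]
n_steps: 500
seed: 1
snapshot_every: 10
vessels_enabled: true
angio:
  s_O2: 1.0
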