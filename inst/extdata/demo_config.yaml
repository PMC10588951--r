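# Demo pipeline config: small synthetic runs of all three stages.
seed: 1
stages:
  simulation:
    genotypes: ["WT", "L102E/L106E"]
    force: 0.05
    duration: 60
    n_seeds: 2
  imaging:
    separations_nm: [132, 365]
    n_seeds: 2
  counts:
    group_a:
      n_tubules: 200
      burst_fraction: 0.015
    group_b:
      n_tubules: 200
      burst_fraction: 0.16
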