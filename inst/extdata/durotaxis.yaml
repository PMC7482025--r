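# Durotaxis study: linear stiffness gradient, 20 Pa/um, start at 6 kPa.
variant: '2.1'
n_mcs: 10000
seed: 1
substrate:
  type: gradient
  E_min: 1.0
  slope: 20.0
  extent: [500.0, 500.0]
  spacing: 2.5
cell:
  center: [250.0, 250.0]
snapshot_interval: 50
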