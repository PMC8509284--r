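# Example study configuration: reduced three-arm design.
cohorts:
  - {group: control, timepoint: none, n: 4}
  - {group: isogenic, timepoint: w3, n: 4}
  - {group: allogenic, timepoint: w3, n: 4}
shape: [64, 64]
protocol:
  snr: 40
roi_voxels: 150
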