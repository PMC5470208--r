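# Demonstration run: a synthetic derivative chromosome fusing two 2-TAD
# parental landscapes inside a TAD on each side.  All sizes are desk-scale.
seed: 7
outDir: demo_out
enzymes:
  primary: GATC
  secondary: GTAC
  minLen: 40
genome:
  meanFragmentLen: 400
landscape:
  binSize: 4000
  tadsA: [[0, 12], [12, 26]]
  tadsB: [[0, 10], [10, 24]]
  breakA: 18
  breakB: 5
  insulation: 2.5
  alpha: 2
  coverage: 100000
  dispersion: 0.1
viewpoints: [3, 10, 16, 22, 30]
params:
  window: 30
  mergeGap: 500
  binSize: 4000
  nModels: 60
  nKeep: 8
  dMin: 1
  dMax: 30
  zCut: -999
  tadSizes: [16000, 24000, 32000, 40000]
  strength: 1.0
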