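# Example pipeline configuration: a reduced-size simulation run.
# Omitted keys take the defaults of defaultPipelineConfig().
seeds:
  simulation: 11
  companion: 12
  proteome: 13
  tissue: 14
  gsea: 15
  coexpression: 16
simulation:
  nGenes: 1000
  deFraction: 0.1
  effectMean: 1.5
  effectSd: 0.25
  replicateNoiseSd: 0.25
companion:
  overlapFraction: 0.3
proteome:
  attenuation: 0.7
  coverage: 0.8
  noiseSd: 0.1
thresholds:
  pMax: 0.05
  minAbsLog2FC: 0.075
enrichment:
  nPermutations: 500
tissue:
  nDonors: 100
  maxGenes: 45
coexpression:
  k: 3
  reference: brain
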