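# Example pipeline configuration for `runPipeline()` / `fdcnet.R run`.
seed: 17
synth:
  nSamples: 60
  shape: [32, 32]
  tumorRadius: 7
preprocess:
  medianKernel: 3
  equalize: false
  highpass: false
  derotate: false
train:
  epochs: 300
  trainFraction: 0.7
  seed: 42
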