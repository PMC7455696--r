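# Demo configuration for the ailqtl CLI: a compact version of the default
# study (smaller intermediate generations) that runs in a few seconds.
seed: 1
generation_sizes: [80, 80, 80, 80, 200]
sharing:
  threshold: 0.4
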