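# Example simulation configuration: 6 V stimulation through a 1000 ohm
# impedance mismatch into the soft-clipping amplifier, 20 s at the default
# rates (4220 Hz tissue grid, 422 Hz recorded output).
brain:
  duration: 20
  seed: 1
stim:
  amplitude: 6
lead:
  Z1: 1000
  Z3: 2000
amp:
  model: soft_clip
adc:
  decimation: 10
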