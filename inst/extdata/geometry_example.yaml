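# Example geometry configuration: a slightly smaller trunk at reduced
# resolution.  Fields not given here keep their defaults.
resolution: [32, 36, 20]
trunk:
  semi_x: 16.0
  semi_z: 10.5
  height: 56.0
layers:
  fat_cm: 0.8
  muscle_cm: 1.0
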