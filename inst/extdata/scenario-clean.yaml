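# Example scenario for the `synth` CLI subcommand: five clean one-minute
# records at 500 Hz. Presets: clean | noisy | ectopic | paced.
preset: clean
n_records: 5
duration: 60
seed: 1
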