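schema: 1
preset: Aos_LOF
grid: [24, 40]
max_ticks: 200
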