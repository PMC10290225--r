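# Total dataset size in bytes without any cluster-specific tooling.
[global]
input_root = "data"

[[global.aggregators]]
name = "total_bytes"
reducer = "sum_size"
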