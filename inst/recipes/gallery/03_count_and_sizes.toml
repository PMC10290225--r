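# Minimal counting recipe: file count plus byte total, in parallel.
[global]
input_root = "data"
parallel = true

[[global.aggregators]]
name = "file_count"
reducer = "count"

[[global.aggregators]]
name = "total_bytes"
reducer = "sum_size"
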