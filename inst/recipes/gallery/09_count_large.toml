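# How many files exceed 256 bytes?
[global]
input_root = "data"

[[global.aggregators]]
name = "large_files"
filter = ["size_at_least", "256"]
reducer = "count"
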