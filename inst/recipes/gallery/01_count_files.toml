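# How many files are in the dataset? (no rules, aggregation only)
[global]
input_root = "data"

[[global.aggregators]]
name = "file_count"
reducer = "count"
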