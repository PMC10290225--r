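# Hidden files hiding in the dataset.
[global]
input_root = "data"

[[global.aggregators]]
name = "hidden_files"
filter = ["all_of", "is_file", "is_hidden"]
reducer = "count"
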