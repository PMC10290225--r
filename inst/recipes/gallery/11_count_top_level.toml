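# Files sitting directly under the input root (depth 1).
[global]
input_root = "data"

[[global.aggregators]]
name = "top_level_files"
filter = ["all_of", "is_file", ["path_depth_is", "1"]]
reducer = "count"
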