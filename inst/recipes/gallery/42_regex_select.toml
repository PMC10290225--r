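# Regex-driven selection into a sorted batch list.
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "media"
filter = ["all_of", "is_file", ["name_matches", '^(img|vol)_[0-9]+\.(png|tif)$']]
reducer = "list_paths"
sink = { kind = "text_list", destination = "out/media.txt" }
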