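# Collect image files only.
[global]
input_root = "data"

[[global.aggregators]]
name = "images"
filter = ["all_of", "is_file", "is_image"]
reducer = "list_paths"
sink = { kind = "text_list", destination = "out/images.txt" }
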