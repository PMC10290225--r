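# Stack 2D z-slices into a 3D volume; z2 stacks before z10 (natural
# sort of the captured index).
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "zstack"
filter = ["all_of", "is_file", ["name_matches", '^z[0-9]+\.tif$']]
reducer = "stack_images"
mapper = "load_image"
sort_key = 'z([0-9]+)'
sink = { kind = "image_file", destination = "out/stack.tif" }
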