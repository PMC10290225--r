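# Maximum intensity projection of the z-slices.
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "mip"
filter = ["all_of", "is_file", ["name_matches", '^z[0-9]+\.tif$']]
reducer = "max_project"
sink = { kind = "image_file", destination = "out/mip.tif" }
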