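# 3D volumes over time stack into a 4D series (t, z, y, x).
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "timeseries"
filter = ["all_of", "is_file", ["name_matches", '^t[0-9]+\.tif$']]
reducer = "stack_images"
sort_key = 't([0-9]+)'
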