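# One projection across every volume of the time series.
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "series_mip"
filter = ["all_of", "is_file", ["name_matches", '^t[0-9]+\.tif$']]
reducer = "max_project"
sink = { kind = "image_file", destination = "out/series_mip.tif" }
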