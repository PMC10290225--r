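# Colocalization metrics between the two channels of one acquisition.
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "channel_coloc"
filter = ["all_of", "is_file", ["name_matches", '_ch[01]\.tif$']]
reducer = "coloc"
sink = { kind = "csv_table", destination = "out/coloc.csv" }
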