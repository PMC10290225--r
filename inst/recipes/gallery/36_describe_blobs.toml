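# Screen segmentation-like output: per-slice statistics and object
# counts over the blob images.
[global]
input_root = "data"
regex_enabled = true

[[global.aggregators]]
name = "blob_stats"
filter = ["all_of", "is_file", ["name_matches", '^b[0-9]+\.tif$']]
reducer = "describe_images"
sink = { kind = "csv_table", destination = "out/blob_stats.csv" }
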