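# Concatenate per-sample measurement tables; identical headers are
# enforced and a provenance column records each row's source file.
[global]
input_root = "data"

[[global.aggregators]]
name = "all_rows"
filter = ["all_of", "is_file", "is_csv"]
reducer = "concat_tables"
sink = { kind = "csv_table", destination = "out/all_rows.csv" }
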