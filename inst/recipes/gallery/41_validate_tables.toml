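# Tables must carry the agreed columns and not be trivially small.
[global]
input_root = "data"

[template.any]
conditions = [["any_of", "not is_csv", ["all_of", ["csv_has_columns", "x", "y"], ["size_at_least", "10"]]]]
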