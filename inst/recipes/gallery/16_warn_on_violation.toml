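# Same contract as 13 but react with warnings instead of failing.
[global]
input_root = "data"
regex_enabled = true

[template.any]
conditions = [["any_of", "is_dir", ["all_of", "not is_hidden", ["name_matches", '^[a-z0-9_]+\.[a-z0-9]+$'], ["any_of", ["not", ["has_extension", ".tif"]], ["image_has_dims", "3"]], ["any_of", ["not", ["has_extension", ".csv"]], ["csv_has_columns", "x", "y"]]]]]
counteractions = [["warn", "layout contract violated"]]
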