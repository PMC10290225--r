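# Full layout contract: visible lowercase single-extension names,
# 3D TIFF volumes, and CSVs carrying the agreed x,y columns.
[global]
input_root = "data"
regex_enabled = true

[template.any]
conditions = [["any_of", "is_dir", ["all_of", "not is_hidden", ["name_matches", '^[a-z0-9_]+\.[a-z0-9]+$'], ["any_of", ["not", ["has_extension", ".tif"]], ["image_has_dims", "3"]], ["any_of", ["not", ["has_extension", ".csv"]], ["csv_has_columns", "x", "y"]]]]]
condition_mode = "all"
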