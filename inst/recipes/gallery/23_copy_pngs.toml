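# Copy every PNG into a flat export folder next to the data.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".png"]]]
actions = [["copy_to", "out_png"]]
counteractions = [["add_to_list", "skipped"]]
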