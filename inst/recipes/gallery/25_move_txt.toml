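# Move stray notes out of the dataset.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".txt"]]]
actions = [["move_to", "moved_txt"]]
counteractions = [["add_to_list", "skipped"]]
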