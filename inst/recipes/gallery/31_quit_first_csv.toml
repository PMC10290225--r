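# Stop the whole traversal as soon as one CSV is found.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".csv"]]]
actions = [["add_to_list", "found"], "quit"]
counteractions = [["add_to_list", "scanned"]]
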