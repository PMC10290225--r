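# Real deletion needs BOTH this flag and --allow-destructive at run
# time; without the second key, remove still quarantines.
[global]
input_root = "data"
destructive_allowed = true

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".tmp"]]]
actions = ["remove"]
counteractions = [["add_to_list", "kept"]]
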