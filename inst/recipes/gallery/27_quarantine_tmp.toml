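# Scratch files are quarantined, not destroyed; the original tree can
# always be restored from the quarantine folder.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".tmp"]]]
actions = ["remove"]
counteractions = [["add_to_list", "kept"]]
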