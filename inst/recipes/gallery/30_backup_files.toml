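# Copy every file into a backup folder (try it with --dry-run first).
[global]
input_root = "data"

[template.any]
conditions = ["is_file"]
actions = [["copy_to", "backup"]]
counteractions = [["add_to_list", "dirs"]]
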