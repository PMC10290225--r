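# Abort on the first naming violation (fail fast on a cluster).
[global]
input_root = "data"
regex_enabled = true

[template.any]
conditions = [["any_of", "is_dir", ["name_matches", '^[a-z0-9_. ]+$']]]
counteractions = [["warn", "bad name"], "quit_on_fail"]
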