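# Names must be lowercase ASCII; directories are exempt.
[global]
input_root = "data"
regex_enabled = true

[template.any]
conditions = [["any_of", "is_dir", ["name_matches", '^[a-z0-9_. ]+$']]]
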