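# Rename in place: spaces to underscores, then lowercase.
[global]
input_root = "data"
regex_enabled = true

[template.any]
conditions = [["all_of", "is_file", ["any_of", ["name_matches", " "], ["name_matches", "[A-Z]"]]]]
actions = [["rename", "whitespace_to_underscore", "to_lowercase"]]
counteractions = [["add_to_list", "untouched"]]
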