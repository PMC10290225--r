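# A depth-1 rule beats the generic any rule.
[global]
input_root = "data"

[template.level_1]
conditions = ["always"]
actions = [["add_to_list", "top"]]

[template.any]
conditions = ["always"]
actions = [["add_to_list", "deeper"]]
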