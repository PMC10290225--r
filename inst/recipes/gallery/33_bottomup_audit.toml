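# Bottom-up traversal: contents are visited before their directory.
[global]
input_root = "data"
traversal_order = "bottomup"

[template.any]
conditions = ["always"]
actions = [["add_to_list", "visited"]]
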