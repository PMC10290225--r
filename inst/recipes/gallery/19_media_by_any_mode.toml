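# condition_mode=any: a node passes when ANY condition holds.
[global]
input_root = "data"

[template.any]
conditions = ["is_csv", "is_image"]
condition_mode = "any"
actions = [["add_to_list", "media"]]
counteractions = [["add_to_list", "other"]]
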