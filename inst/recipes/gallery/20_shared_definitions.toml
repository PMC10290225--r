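# Reusable alias declared once in the global section.
[global]
input_root = "data"

[global.shared_definitions]
image_file = ["all_of", "is_file", "is_image"]

[template.any]
conditions = ["image_file"]
actions = [["add_to_list", "imgs"]]
counteractions = [["add_to_list", "rest"]]
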