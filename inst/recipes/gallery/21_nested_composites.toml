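# Composites pair with composites: double negation of a disjunction.
[global]
input_root = "data"

[template.any]
conditions = [["not", ["not", ["any_of", ["all_of", "is_file", ["has_extension", ".png"]], ["all_of", "is_file", ["has_extension", ".tif"]]]]]]
actions = [["add_to_list", "pics"]]
counteractions = [["add_to_list", "other"]]
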