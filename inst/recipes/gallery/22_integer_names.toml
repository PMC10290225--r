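# Plate folders must be numbered; collect the numbered ones.
[global]
input_root = "data"

[template.level_1]
conditions = ["name_is_integer"]
actions = [["add_to_list", "plates"]]
counteractions = [["add_to_list", "unnumbered"]]
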