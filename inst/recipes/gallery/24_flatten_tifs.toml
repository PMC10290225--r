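# Flatten TIFFs from nested folders; names derive from the full path
# so equal basenames cannot collide.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", ["has_extension", ".tif"]]]
actions = [["flatten_to", "flat"]]
counteractions = [["add_to_list", "skipped"]]
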