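# act_on_success=false: the action list fires on FAILING nodes,
# collecting every violator into a named list.
[global]
input_root = "data"
regex_enabled = true
act_on_success = false

[template.any]
conditions = [["any_of", "is_dir", ["all_of", "not is_hidden", ["name_matches", '^[a-z0-9_]+\.[a-z0-9]+$']]]]
actions = [["add_to_list", "violations"]]
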