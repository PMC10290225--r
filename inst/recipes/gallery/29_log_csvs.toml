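# Annotated logging: append every CSV path to a log file.
[global]
input_root = "data"

[template.any]
conditions = [["all_of", "is_file", "is_csv"]]
actions = [["log_to_file", "out/csv_log.txt"]]
counteractions = [["add_to_list", "skipped"]]
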