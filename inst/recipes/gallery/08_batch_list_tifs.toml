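# Preprocessed batch list of TIFF stacks for a downstream pipeline.
[global]
input_root = "data"

[[global.aggregators]]
name = "tif_batch"
filter = ["all_of", "is_file", ["has_extension", ".tif"]]
reducer = "list_paths"
sink = { kind = "text_list", destination = "out/tif_batch.txt" }
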