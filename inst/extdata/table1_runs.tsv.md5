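6a39e2163fdcf5236d299163bdbc56b5  table1_runs.tsv
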