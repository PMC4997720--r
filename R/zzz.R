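utils::globalVariables(c(".data", "victory_rate", "median", "iqr",
                         "mean_shrinkage"))
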