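utils::globalVariables(c("t_s", "current_uA", "target_uA", "channel",
                         "dose_g", "x", "y"))
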