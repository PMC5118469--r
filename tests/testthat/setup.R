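op <- options(rkcca.verbose = FALSE)
withr::defer(options(op), teardown_env())
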