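# small deterministic per-plot seed for repeated-run studies
.plot_seed_test <- function(master, i) as.integer((master + 131 * i) %% 2147483647)
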