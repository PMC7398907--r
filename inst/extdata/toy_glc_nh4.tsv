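exchange	uptake
EX_glc	10
EX_nh4	10
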