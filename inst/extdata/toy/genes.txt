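gene00001
gene00002
gene00003
gene00004
gene00005
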