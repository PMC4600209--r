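hc_item,ca_item,concept
H3,D5,ADL decline
H5,D4D,Stair climbing
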