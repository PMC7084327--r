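HR02
HR03
HR04
HR05
HR09
HR11
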