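sample	gene	ct
control	Actb	15.1
control	Pten	24.3
control	Bim	26.0
transfected	Actb	15.2
transfected	Pten	23.1
transfected	Bim	27.4
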