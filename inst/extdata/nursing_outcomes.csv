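group,n,effective,markedly_effective,ineffective,complications
experimental,25,13,10,2,2
control,25,10,10,5,4
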