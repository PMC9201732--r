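group,measure,mean,sd,n,unit
experimental,sensory_block,7.53,1.47,25,h
control,sensory_block,3.38,1.26,25,h
experimental,motor_block,5.45,1.36,25,h
control,motor_block,3.02,1.31,25,h
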