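group,n,complication,count
experimental,25,deep_vein_thrombosis,2
control,25,deep_vein_thrombosis,2
control,25,screw_fell_off,1
control,25,fixation_rupture,1
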