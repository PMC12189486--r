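class,n_cycles
normal,13905
systolic,10849
diastolic,1625
abnormal,4183
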