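diagnosis,n_recordings,mean_duration_s
Normal,401,18.32
Aortic regurgitation,172,25.06
Aortic stenosis,104,25.69
Pulmonic stenosis,17,20.81
Pulmonary regurgitation,19,19.89
Tricuspid stenosis,18,19.95
Tricuspid regurgitation,147,23.52
Mitral stenosis,100,25.27
Mitral regurgitation,375,24.61
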