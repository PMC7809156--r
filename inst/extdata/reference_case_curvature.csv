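case,group,area,mean_curvature
S1,schizophrenia,BA22,1.08
S1,schizophrenia,BA24,0.46
S4,schizophrenia,BA22,0.36
S4,schizophrenia,BA24,0.71
N2,control,BA22,0.58
N2,control,BA24,0.44
N4,control,BA22,0.35
N4,control,BA24,0.41
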