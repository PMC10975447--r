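response,form,term,reported_slope
saor_deg,2FI,x4,-2.46
ft_s,quadratic,x4,-4.01
wavelength_frames,reduced_linear,x4,-1.82
count,reduced_linear,x4,2.71
a_plus_b,linear,x4,2.70
aufc,reduced_quadratic,x4,805.76
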