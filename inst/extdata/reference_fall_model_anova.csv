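source,sumsq,meansq,f,p_value
total,0.014705,0.0009803,,
model,0.012228,0.0024457,9.8737,0.001268
residual,0.002477,0.0002477,,
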