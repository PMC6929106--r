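cell_line,o2_percent,hrf
A549,1,1.60
H460,1,1.24
H1437,1,1.09
B16F10,1,1.29
Renca,1,1.28
A549,0.5,2.04
H460,0.5,1.44
H1437,0.5,1.33
B16F10,0.5,1.44
Renca,0.5,1.67
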