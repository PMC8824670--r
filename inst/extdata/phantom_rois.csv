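label,x0,y0,width,height
high,0,0,1500,900
low,1500,0,1500,900
negative,3000,0,1500,900
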