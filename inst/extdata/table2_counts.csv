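group,n,alf,death_or_lt
ALT_MONO,130,0,0
TB_MONO,25,2,2
DOP,228,4,0
DSP,221,22,11
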