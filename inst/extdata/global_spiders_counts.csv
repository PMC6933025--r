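category,Literature,GBIF,Combined
DD,120,165,109
CR,3,2,6
EN,10,3,10
VU,4,0,6
NT,3,0,3
LC,60,30,66
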