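category,Literature,GBIF,Combined
DD,117,260,112
CR,17,4,16
EN,53,7,55
VU,29,3,28
NT,5,0,7
LC,58,5,61
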