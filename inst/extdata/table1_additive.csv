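id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1,2.1,*,,,,,,
OsMADS50,-6.1,**,-1.9,**,,,,
Hd3a,5.6,**,,,,,,
Hd1,,,,,,,,
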