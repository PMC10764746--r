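id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1,2.7,**,-2.3,*,2.6,*,,
OsMADS50,-8.0,**,,,,,,
Hd3a,18.5,**,-2.4,*,,,,
Hd1,1.7,*,,,,,,
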