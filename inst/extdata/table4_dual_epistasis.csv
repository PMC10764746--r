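id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1-1/OsMADS50-1,3.5,*,-3.4,*,,,,
Ehd1-2/OsMADS50-1,2.7,**,,,,,,
Ehd1-1/OsMADS50-2,-3.2,**,,,,,,
Ehd1-2/OsMADS50-2,,,,,,,,
Ehd1-1/Hd3a-1,-15.2,**,,,,,,
Ehd1-2/Hd3a-1,-12.2,**,3.7,*,,,,
Ehd1-1/Hd3a-2,13.0,**,-3.5,*,,,,
Ehd1-2/Hd3a-2,16.2,**,4.1,*,,,,
Ehd1-1/Hd1-1,-3.4,**,3.3,*,-3.1,*,,
Ehd1-2/Hd1-1,,,,,,,,
Ehd1-1/Hd1-2,,,,,,,,
Ehd1-2/Hd1-2,,,,,,,,
OsMADS50-1/Hd3a-1,-13.5,**,3.5,*,,,,
OsMADS50-2/Hd3a-1,-18.6,**,,,,,,
OsMADS50-1/Hd3a-2,7.2,**,,,,,,
OsMADS50-2/Hd3a-2,6.4,**,-3.6,*,,,,
OsMADS50-1/Hd1-1,,,,,,,,
OsMADS50-2/Hd1-1,-4.6,**,,,,,,
OsMADS50-1/Hd1-2,-7.6,**,,,,,,
OsMADS50-2/Hd1-2,-4.4,**,,,,,,
Hd3a-1/Hd1-1,-15.3,**,,,,,,
Hd3a-2/Hd1-1,9.1,**,5.0,**,-7.1,**,,
Hd3a-1/Hd1-2,,,,,,,,
Hd3a-2/Hd1-2,6.6,**,7.3,**,-9.7,**,,
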