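id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1-1/OsMADS50-1/Hd3a-1,-13.4,**,-4.5,*,,,,
Ehd1-1/OsMADS50-1/Hd3a-2,19.1,**,,,,,,
Ehd1-1/OsMADS50-1/Hd1-1,-3.0,*,,,,,,
Ehd1-1/OsMADS50-1/Hd1-2,,,,,,,,
Ehd1-1/OsMADS50-2/Hd3a-1,-18.0,**,,,,,,
Ehd1-1/OsMADS50-2/Hd3a-2,-5.3,**,,,,,,
Ehd1-1/OsMADS50-2/Hd1-1,-3.8,**,,,,,,
Ehd1-1/OsMADS50-2/Hd1-2,-6.2,**,4.8,*,-5.3,*,,
Ehd1-1/Hd3a-1/Hd1-1,-17.6,**,-4.8,*,,,,
Ehd1-1/Hd3a-1/Hd1-2,-16.4,**,,,,,,
Ehd1-1/Hd3a-2/Hd1-1,9.9,**,4.4,*,-6.7,**,,
Ehd1-1/Hd3a-2/Hd1-2,10.2,**,,,,,,
Ehd1-2/OsMADS50-1/Hd3a-1,-11.8,**,-4.8,*,5.9,*,,
Ehd1-2/OsMADS50-1/Hd3a-2,13.6,**,,,,,,
Ehd1-2/OsMADS50-1/Hd1-1,,,,,,,,
Ehd1-2/OsMADS50-1/Hd1-2,,,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-1,-15.6,**,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-2,7.6,**,,,,,,
Ehd1-2/OsMADS50-2/Hd1-1,-3.1,*,,,,,,
Ehd1-2/OsMADS50-2/Hd1-2,-2.7,**,-4.8,*,,,,
Ehd1-2/Hd3a-1/Hd1-1,-12.8,**,,,,,,
Ehd1-2/Hd3a-1/Hd1-2,-13.6,**,,,,,,
Ehd1-2/Hd3a-2/Hd1-1,13.3,**,-4.6,*,,,,
Ehd1-2/Hd3a-2/Hd1-2,15.1,**,,,,,,
OsMADS50-1/Hd3a-1/Hd1-1,-16.0,**,,,,,,
OsMADS50-1/Hd3a-1/Hd1-2,-14.2,**,4.4,*,,,,
OsMADS50-1/Hd3a-2/Hd1-1,3.6,**,-4.4,*,,,,
OsMADS50-1/Hd3a-2/Hd1-2,6.2,**,,,,,,
OsMADS50-2/Hd3a-1/Hd1-1,-18.5,**,,,,,,
OsMADS50-2/Hd3a-1/Hd1-2,-18.5,**,,,,,,
OsMADS50-2/Hd3a-2/Hd1-1,8.2,**,-5.3,*,,,,
OsMADS50-2/Hd3a-2/Hd1-2,4.2,*,,,,,,
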