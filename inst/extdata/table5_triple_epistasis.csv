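id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1-1/OsMADS50-1/Hd3a-1,16.8,**,-5.6,*,7.5,**,,
Ehd1-1/OsMADS50-1/Hd3a-2,-9.7,**,7.4,**,,,,
Ehd1-1/OsMADS50-1/Hd1-1,,,,,,,,
Ehd1-1/OsMADS50-1/Hd1-2,8.9,**,,,,,,
Ehd1-1/OsMADS50-2/Hd3a-1,19.0,**,,,,,,
Ehd1-1/OsMADS50-2/Hd3a-2,-9.3,**,-6.0,*,,,,
Ehd1-1/OsMADS50-2/Hd1-1,4.8,**,,,,,,
Ehd1-1/OsMADS50-2/Hd1-2,3.3,*,,,,,,
Ehd1-1/Hd3a-1/Hd1-1,16.3,**,,,,,,
Ehd1-1/Hd3a-1/Hd1-2,,,,,,,,
Ehd1-1/Hd3a-2/Hd1-1,-8.8,**,-5.9,*,7.0,**,,
Ehd1-1/Hd3a-2/Hd1-2,-7.5,**,-5.7,*,9.0,**,,
Ehd1-2/OsMADS50-1/Hd3a-1,11.1,**,,,,,,
Ehd1-2/OsMADS50-1/Hd3a-2,-12.6,**,,,,,,
Ehd1-2/OsMADS50-1/Hd1-1,,,,,,,,
Ehd1-2/OsMADS50-1/Hd1-2,6.4,**,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-1,14.0,**,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-2,-8.7,**,,,,,,
Ehd1-2/OsMADS50-2/Hd1-1,4.5,**,,,,,,
Ehd1-2/OsMADS50-2/Hd1-2,,,,,,,,
Ehd1-2/Hd3a-1/Hd1-1,16.6,**,,,,,,
Ehd1-2/Hd3a-1/Hd1-2,,,,,,,,
Ehd1-2/Hd3a-2/Hd1-1,-10.1,**,-5.5,*,6.8,**,,
Ehd1-2/Hd3a-2/Hd1-2,-8.2,**,-5.3,*,9.0,**,,
OsMADS50-1/Hd3a-1/Hd1-1,13.1,**,,,,,,
OsMADS50-1/Hd3a-1/Hd1-2,8.6,**,,,,,,
OsMADS50-1/Hd3a-2/Hd1-1,-12.5,**,,,,,,
OsMADS50-1/Hd3a-2/Hd1-2,-7.0,**,10.7,**,,,,
OsMADS50-2/Hd3a-1/Hd1-1,20.0,**,,,,,,
OsMADS50-2/Hd3a-1/Hd1-2,6.1,**,,,,,,
OsMADS50-2/Hd3a-2/Hd1-1,-6.0,**,-5.1,*,5.7,*,,
OsMADS50-2/Hd3a-2/Hd1-2,-4.2,**,-10.4,**,12.6,**,,
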