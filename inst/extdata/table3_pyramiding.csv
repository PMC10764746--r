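id,value,stars,e1,e1_stars,e2,e2_stars,e3,e3_stars
Ehd1-1/OsMADS50-1,-6.8,**,3.2,*,,,,
Ehd1-1/OsMADS50-2,-6.6,**,,,,,,
Ehd1-1/Hd3a-1,6.0,**,3.2,*,,,,
Ehd1-1/Hd3a-2,21.3,**,,,,,,
Ehd1-1/Hd1-1,,,,,,,,
Ehd1-1/Hd1-2,1.7,*,-2.9,*,3.2,*,,
Ehd1-2/OsMADS50-1,-3.9,**,-3.4,**,,,,
Ehd1-2/OsMADS50-2,-5.9,**,-2.6,*,,,,
Ehd1-2/Hd3a-1,7.6,**,-2.8,*,2.5,*,,
Ehd1-2/Hd3a-2,23.2,**,-4.4,**,2.5,*,,
Ehd1-2/Hd1-1,,,,,,,,
Ehd1-2/Hd1-2,2.7,**,-2.9,*,2.6,*,,
OsMADS50-1/Hd3a-1,-3.0,**,,,,,,
OsMADS50-1/Hd3a-2,4.8,**,,,,,,
OsMADS50-1/Hd1-1,-6.6,**,,,,,,
OsMADS50-1/Hd1-2,-7.6,**,2.6,*,,,,
OsMADS50-2/Hd3a-1,-6.2,**,,,,,,
OsMADS50-2/Hd3a-2,3.6,**,-2.8,*,,,,
OsMADS50-2/Hd1-1,-9.0,**,,,,,,
OsMADS50-2/Hd1-2,-9.5,**,,,,,,
Hd3a-1/Hd1-1,4.9,**,,,,,,
Hd3a-1/Hd1-2,5.7,**,,,,,,
Hd3a-2/Hd1-1,16.4,**,2.7,*,-4.9,**,,
Hd3a-2/Hd1-2,13.1,**,5.7,**,-7.9,**,,
Ehd1-1/OsMADS50-1/Hd3a-1,-5.6,**,6.0,**,,,,
Ehd1-1/OsMADS50-1/Hd3a-2,9.4,**,-3.1,*,3.1,*,,
Ehd1-1/OsMADS50-1/Hd1-1,-6.6,**,,,,,,
Ehd1-1/OsMADS50-1/Hd1-2,-6.5,**,2.5,*,,,,
Ehd1-1/OsMADS50-2/Hd3a-1,-2.9,**,,,,,,
Ehd1-1/OsMADS50-2/Hd3a-2,3.9,**,,,,,,
Ehd1-1/OsMADS50-2/Hd1-1,-8.2,**,,,,,,
Ehd1-1/OsMADS50-2/Hd1-2,-8.7,**,,,,,,
Ehd1-1/Hd3a-1/Hd1-1,5.3,**,,,,,,
Ehd1-1/Hd3a-1/Hd1-2,5.7,**,,,,,,
Ehd1-1/Hd3a-2/Hd1-1,19.9,**,,,,,,
Ehd1-1/Hd3a-2/Hd1-2,19.4,**,,,,,,
Ehd1-2/OsMADS50-1/Hd3a-1,-4.7,**,2.5,*,,,,
Ehd1-2/OsMADS50-1/Hd3a-2,12.5,**,-4.2,**,2.9,*,,
Ehd1-2/OsMADS50-1/Hd1-1,-5.2,**,3.0,*,,,,
Ehd1-2/OsMADS50-1/Hd1-2,-3.8,**,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-1,-1.9,*,,,,,,
Ehd1-2/OsMADS50-2/Hd3a-2,8.4,**,-3.1,*,,,,
Ehd1-2/OsMADS50-2/Hd1-1,-6.2,**,,,,,,
Ehd1-2/OsMADS50-2/Hd1-2,-6.6,**,3.0,*,,,,
Ehd1-2/Hd3a-1/Hd1-1,8.7,**,-2.9,*,2.6,*,,
Ehd1-2/Hd3a-1/Hd1-2,7.1,**,,,,,,
Ehd1-2/Hd3a-2/Hd1-1,21.9,**,,,,,,
Ehd1-2/Hd3a-2/Hd1-2,22.9,**,-2.5,*,,,,
OsMADS50-1/Hd3a-1/Hd1-1,-3.8,**,,,,,,
OsMADS50-1/Hd3a-1/Hd1-2,-2.8,**,2.7,*,,,,
OsMADS50-1/Hd3a-2/Hd1-1,2.9,**,,,,,,
OsMADS50-1/Hd3a-2/Hd1-2,4.7,**,,,,,,
OsMADS50-2/Hd3a-1/Hd1-1,-4.4,**,,,,,,
OsMADS50-2/Hd3a-1/Hd1-2,-5.2,**,,,,,,
OsMADS50-2/Hd3a-2/Hd1-1,4.0,**,-2.6,*,,,,
OsMADS50-2/Hd3a-2/Hd1-2,,,,,,,,
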