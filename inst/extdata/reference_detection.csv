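experiment,image_id,tp,fp,fn,recall,precision
A,05447,107,4,5,0.96,0.96
A,05453,100,3,1,0.99,0.97
A,05459,43,7,4,0.91,0.86
A,05465,73,0,3,0.96,1.00
A,60537,112,4,6,0.95,0.97
A,55522,103,2,5,0.95,0.98
A,78990,99,3,3,0.97,0.97
B,01099,84,13,13,0.87,0.87
B,05247,97,0,7,0.93,1.00
B,05255,80,15,9,0.90,0.84
B,05349,96,6,6,0.94,0.94
B,05355,76,0,6,0.93,1.00
B,05361,128,0,13,0.91,1.00
B,05367,130,5,16,0.89,0.96
Overall,Overall,1328,62,97,0.93,0.96
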