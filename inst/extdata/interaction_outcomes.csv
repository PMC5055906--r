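drug_id,interval_min,rd_pct,ra_pct,observed
amlodipine,1,14.2,1.0,NE
amlodipine,30,99.0,26.8,NE
amlodipine,90,100.0,60.8,E
amlodipine,240,100.0,91.8,E
bufferin,1,15.3,2.6,NE
bufferin,60,100.0,78.8,E
losartan,30,84.8,21.7,NE
losartan,60,97.7,61.6,E
metoprolol_er,1,0.6,0.2,NE
metoprolol_er,60,30.9,10.7,NE
nifedipine,1,10.0,0.0,E
nifedipine,30,95.8,41.6,E
nifedipine,120,99.8,98.6,E
triazolam,1,8.4,0.0,NE
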