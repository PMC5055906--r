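drug_id,kd_ph12_per_s,kd_ph68_per_s,tlagd_h,ka_per_h,tlaga_h,dissolution_complete
amlodipine,2.554e-3,3.99e-4,0,0.62,0,TRUE
bufferin,1.100e-3,2.764e-3,0,1.55,0,TRUE
losartan,6.0e-5,1.05e-3,0,1.43,0.33,TRUE
metoprolol_er,1.03e-4,7.6e-5,0,0.11,0,TRUE
nifedipine,1.759e-3,1.158e-3,0,2.49,0.28,TRUE
triazolam,1.469e-3,1.108e-3,0,17.34,0.44,TRUE
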