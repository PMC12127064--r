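cluster,label,n_without,pct_without,n_with,pct_with,decrease_n,decrease_pct,z
Re,Re-experiencing in the here and now,320,32.8,221,22.7,99,30.8,9.95
Av,Avoidance,353,36.2,286,29.3,67,19.1,8.19
Th,Sense of threat,367,37.6,235,24.1,132,35.9,11.49
PTSD_FI,PTSD functional impairment,267,27.4,192,19.7,75,28.1,8.66
AD,Affective dysregulation,418,42.9,318,32.6,100,24.0,10.00
NSC,Negative self-concept,295,30.3,238,24.4,57,19.5,7.55
DR,Disturbed relationships,350,35.9,268,27.5,82,23.4,9.06
DSO_FI,DSO functional impairment,282,28.9,204,20.9,78,27.7,8.83
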