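item,label,variant,n_without,pct_without,n_with,pct_with,decrease_n,decrease_pct,z
ptsd_re1,Nightmares,1,247,25.3,146,15.0,101,40.7,10.05
ptsd_re2,Flashbacks,1,242,24.8,172,17.6,70,29.0,8.37
ptsd_av1,Internal avoidance,1,281,28.8,230,23.6,51,18.1,7.14
ptsd_av2,External avoidance,1,268,27.5,185,19.0,83,30.9,9.11
ptsd_th1,Hyperalert,1,320,32.8,179,18.4,41,43.9,11.87
ptsd_th2,Hyperarousal,1,243,24.9,182,18.7,61,24.9,7.81
PTSD_FI,PTSD functional impairment,1,267,27.4,192,19.7,75,28.1,8.66
dso_ad1,Difficulty calming down,1,347,35.6,257,26.4,90,25.8,9.49
dso_ad2,Numbing,1,285,29.2,191,19.6,94,32.9,9.70
dso_ad2,Numbing,2,285,29.2,209,21.4,76,26.7,8.72
dso_nsc1,Feel like a failure,1,249,25.5,204,20.9,45,18.0,6.71
dso_nsc2,Feel worthless,1,233,23.9,182,18.7,51,21.8,7.14
dso_dr1,Feel cut off from others,1,274,28.1,221,22.7,53,19.2,7.28
dso_dr1,Feel cut off from others,2,274,28.1,203,20.8,71,26.0,8.43
dso_dr2,Difficult close to others,1,271,27.8,209,21.4,62,23.0,7.87
DSO_FI,DSO functional impairment,1,282,28.9,204,20.9,78,27.7,8.83
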