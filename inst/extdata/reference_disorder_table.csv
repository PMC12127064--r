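disorder,n_without,pct_without,n_with,pct_with,decrease_pct,z,monotone
PTSD,53,5.4,37,3.8,29.6,2.17,FALSE
CPTSD,93,9.5,48,4.9,48.4,6.56,TRUE
either,146,14.9,85,8.7,41.6,7.68,TRUE
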