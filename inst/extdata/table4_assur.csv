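tech_id,panel_id,target,mean_score
A,SP,influenza A,0.65
A,SP,M. tuberculosis,0.67
A,BL,MS2,0.68
A,BL,S. pneumoniae,0.68
A,ST,MS2,0.61
A,ST,S. Typhimurium,0.64
B,SP,influenza A,0.54
B,SP,M. tuberculosis,0.62
B,BL,MS2,0.61
B,BL,S. pneumoniae,0.71
B,ST,MS2,0.74
B,ST,S. Typhimurium,0.69
C,SP,influenza A,0.80
C,SP,M. tuberculosis,0.78
C,BL,MS2,0.68
C,BL,S. pneumoniae,0.75
C,ST,MS2,0.63
C,ST,S. Typhimurium,0.56
D,SP,influenza A,0.44
D,SP,M. tuberculosis,0.49
D,BL,MS2,0.50
D,BL,S. pneumoniae,0.61
D,ST,MS2,0.59
D,ST,S. Typhimurium,0.60
E,SP,influenza A,0.72
E,SP,M. tuberculosis,0.72
E,BL,MS2,0.65
E,BL,S. pneumoniae,0.66
E,ST,MS2,0.59
E,ST,S. Typhimurium,0.57
F,SP,influenza A,0.75
F,SP,M. tuberculosis,0.75
F,BL,MS2,0.80
F,BL,S. pneumoniae,0.82
F,ST,MS2,0.76
F,ST,S. Typhimurium,0.74
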