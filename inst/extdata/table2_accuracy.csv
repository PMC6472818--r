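panel_id,target,tech_id,sensitivity,sens_lower,sens_upper,specificity,spec_lower,spec_upper,rank
SP,influenza A,A,0.75,0.58,0.88,1.00,0.92,1.00,3
SP,influenza A,B,0.00,0.00,0.10,1.00,0.92,1.00,5
SP,influenza A,C,1.00,0.90,1.00,1.00,0.92,1.00,1
SP,influenza A,D,0.00,0.00,0.10,1.00,0.92,1.00,6
SP,influenza A,E,0.86,0.71,0.95,0.93,0.82,0.99,2
SP,influenza A,F,0.75,0.58,0.88,1.00,0.92,1.00,3
SP,M. tuberculosis,A,1.00,0.92,1.00,0.86,0.71,0.95,1
SP,M. tuberculosis,B,0.40,0.26,0.56,1.00,0.90,1.00,5
SP,M. tuberculosis,C,0.86,0.71,0.95,1.00,0.90,1.00,1
SP,M. tuberculosis,D,0.33,0.20,0.49,0.92,0.78,0.98,6
SP,M. tuberculosis,E,0.76,0.60,0.87,1.00,0.90,1.00,3
SP,M. tuberculosis,F,0.71,0.56,0.84,1.00,0.90,1.00,4
BL,MS2,A,1.00,0.92,1.00,1.00,0.92,1.00,1
BL,MS2,B,0.93,0.82,0.99,0.02,0.00,0.12,6
BL,MS2,C,0.36,0.22,0.51,1.00,0.92,1.00,4
BL,MS2,D,0.07,0.01,0.18,1.00,0.92,1.00,5
BL,MS2,E,0.87,0.73,0.95,1.00,0.92,1.00,3
BL,MS2,F,1.00,0.92,1.00,0.98,0.88,1.00,2
BL,S. pneumoniae,A,1.00,0.92,1.00,1.00,0.92,1.00,1
BL,S. pneumoniae,B,0.60,0.44,0.74,1.00,0.92,1.00,5
BL,S. pneumoniae,C,0.73,0.58,0.85,1.00,0.92,1.00,4
BL,S. pneumoniae,D,0.60,0.44,0.74,1.00,0.92,1.00,5
BL,S. pneumoniae,E,0.96,0.85,0.99,1.00,0.85,0.99,2
BL,S. pneumoniae,F,0.98,0.88,1.00,0.91,0.79,0.98,3
ST,MS2,A,0.84,0.71,0.94,1.00,0.92,1.00,1
ST,MS2,B,0.60,0.44,0.74,0.53,0.38,0.68,6
ST,MS2,C,0.73,0.58,0.85,1.00,0.92,1.00,3
ST,MS2,D,0.60,0.44,0.74,1.00,0.92,1.00,5
ST,MS2,E,0.67,0.50,0.80,1.00,0.92,1.00,4
ST,MS2,F,0.80,0.65,0.90,1.00,0.92,1.00,2
ST,S. Typhimurium,A,1.00,0.92,1.00,1.00,0.92,1.00,1
ST,S. Typhimurium,B,0.60,0.44,0.74,1.00,0.92,1.00,3
ST,S. Typhimurium,C,0.40,0.26,0.56,1.00,0.92,1.00,6
ST,S. Typhimurium,D,0.64,0.49,0.78,1.00,0.92,1.00,2
ST,S. Typhimurium,E,0.57,0.41,0.72,1.00,0.92,1.00,5
ST,S. Typhimurium,F,0.60,0.44,0.70,1.00,0.92,1.00,3
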