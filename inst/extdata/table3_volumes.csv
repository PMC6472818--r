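group,panel_id,specimen,na_extracted,input_volume,provided_volume,elution_volume,pct_of_total_sample,pct_eluate_per_pcr,pct_sample_per_pcr
PATH,SP,sputum,DNA,500,500,100,100,5.0,5.0
PATH,SP,sputum,RNA,140,500,60,28,8.3,2.3
PATH,BL,blood,DNA,200,1000,200,20,2.5,0.5
PATH,BL,blood,RNA,140,1000,60,14,8.3,1.2
PATH,ST,stool,DNA,200,1000,200,20,2.5,0.5
PATH,ST,stool,RNA,28,1000,60,3,8.3,0.2
CDC,SP,sputum,DNA/RNA,300,500,100,60,5.0,3.0
CDC,BL,blood,DNA/RNA,225.8,1000,100,23,5.0,1.2
CDC,ST,stool,DNA/RNA,22.6,1000,100,2,5.0,0.1
A,SP,sputum,DNA/RNA,500,500,105,100,4.8,4.8
A,BL,blood,DNA/RNA,1000,1000,105,100,4.8,4.8
A,ST,stool,DNA/RNA,750,1000,105,75,4.8,3.6
B,SP,sputum,DNA/RNA,500,500,150,100,3.3,3.3
B,BL,blood,DNA/RNA,100,1000,150,10,3.3,0.3
B,ST,stool,DNA/RNA,250,1000,150,25,3.3,0.8
C,SP,sputum,DNA/RNA,150,500,50,30,10.0,3.0
C,BL,blood,DNA/RNA,50,1000,50,5,10.0,0.5
C,ST,stool,DNA/RNA,70,1000,50,7,10.0,0.7
D,SP,sputum,DNA/RNA,80,500,100,16,5.0,0.8
D,BL,blood,DNA/RNA,80,1000,100,8,5.0,0.4
D,ST,stool,DNA/RNA,80,1000,100,8,5.0,0.4
E,SP,sputum,DNA/RNA,100,500,50,20,10.0,2.0
E,BL,blood,DNA/RNA,100,1000,50,10,10.0,1.0
E,ST,stool,DNA/RNA,77,1000,50,8,10.0,0.8
F,SP,sputum,DNA/RNA,500,500,100,100,5.0,5.0
F,BL,blood,DNA/RNA,250,1000,100,25,5.0,1.3
F,ST,stool,DNA/RNA,150,1000,100,15,5.0,0.8
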