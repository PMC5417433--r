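year,species,dbh_mean,dbh_se,phloem_mean,phloem_se,phloem_letter,n
2013,ponderosa,25.76,0.58,2.02,0.08,,4
2013,lodgepole,24.28,0.57,2.01,0.07,,4
2013,jack,22.63,0.71,1.56,0.04,,4
2013,red,24.63,1.30,1.89,0.04,,4
2013,eastern_white,24.60,0.78,1.86,0.06,,4
2013,scots,24.03,0.90,1.61,0.03,,4
2014,ponderosa,24.22,0.21,3.10,0.06,a,4
2014,lodgepole,23.61,0.48,3.18,0.05,a,4
2014,jack,22.93,0.55,2.00,0.06,c,4
2014,red,23.10,0.36,2.47,0.04,b,4
2014,eastern_white,24.13,0.63,2.50,0.10,b,4
2014,scots,23.56,0.93,2.09,0.07,bc,4
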