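year,column,F,df_num,df_den,P
2013,dbh,1.46,5,18,0.25
2013,phloem,2.61,5,18,0.06
2014,dbh,0.83,5,18,0.54
2014,phloem,12.51,5,18,0.0001
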