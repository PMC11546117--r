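substrate,direction,experiment,median,code
atenolol,A2B,1,0.38,
atenolol,A2B,2,0.03,
atenolol,A2B,3,0.28,
atenolol,B2A,1,0.63,
atenolol,B2A,2,0.41,
atenolol,B2A,3,0.51,
CDF(DA),A2B,1,,a
CDF(DA),A2B,2,0.17,b
CDF(DA),A2B,3,,a
CDF(DA),B2A,1,,a
CDF(DA),B2A,2,0.17,
CDF(DA),B2A,3,0.31,
fexofenadine,A2B,1,0.28,
fexofenadine,A2B,2,0.11,
fexofenadine,A2B,3,0.23,
fexofenadine,B2A,1,0.44,
fexofenadine,B2A,2,0.32,
fexofenadine,B2A,3,0.41,
metformin,A2B,1,0.86,
metformin,A2B,2,0.11,c
metformin,A2B,3,0.11,c
metformin,B2A,1,0.85,
metformin,B2A,2,0.05,c
metformin,B2A,3,0.05,c
methotrexate,A2B,1,0.20,
methotrexate,A2B,2,0.11,c
methotrexate,A2B,3,0.11,c
methotrexate,B2A,1,0.35,
methotrexate,B2A,2,0.05,c
methotrexate,B2A,3,0.05,c
propranolol,A2B,1,7.65,
propranolol,A2B,2,15.73,
propranolol,A2B,3,18.18,
propranolol,B2A,1,5.73,
propranolol,B2A,2,11.62,
propranolol,B2A,3,14.30,
sulfasalazine,A2B,1,,a
sulfasalazine,A2B,2,0.11,c
sulfasalazine,A2B,3,,a
sulfasalazine,B2A,1,0.43,
sulfasalazine,B2A,2,0.19,
sulfasalazine,B2A,3,0.23,
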