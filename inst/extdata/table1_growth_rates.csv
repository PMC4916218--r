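treatment,donor,sulfate_mM,strain,mu_avg,mu_sem
Pyruvate + sulfate,pyruvate,40,wild-type,0.154,0.029
Pyruvate + sulfate,pyruvate,40,nfnA-2,0.172,0.029
Pyruvate + sulfate,pyruvate,40,nfnB-2,0.168,0.035
Malate + sulfate,malate,40,wild-type,0.067,0.007
Malate + sulfate,malate,40,nfnA-2,0.014,0.006
Malate + sulfate,malate,40,nfnB-2,0.015,0.004
Fumarate + sulfate,fumarate,40,wild-type,0.085,0.012
Fumarate + sulfate,fumarate,40,nfnA-2,0.011,0.002
Fumarate + sulfate,fumarate,40,nfnB-2,0.007,0.006
Fumarate fermentation,fumarate,0,wild-type,0.057,0.007
Fumarate fermentation,fumarate,0,nfnA-2,0.010,0.002
Fumarate fermentation,fumarate,0,nfnB-2,0.015,0.004
Pyruvate fermentation,pyruvate,0,wild-type,0.131,0.007
Pyruvate fermentation,pyruvate,0,nfnA-2,0.120,0.001
Pyruvate fermentation,pyruvate,0,nfnB-2,0.149,0.012
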