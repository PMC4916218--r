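compound,class,n_carbon,branching,n_double_bonds,n_carboxyl,h_total_acid,h_nonexch_acid,h_methyl_added,h_fame,h_primer
n-C14:0,fatty_acid,14,normal,0,1,28,27,3,30,3
i-C15:0,fatty_acid,15,iso,0,1,30,29,3,32,9
a-C15:0,fatty_acid,15,anteiso,0,1,30,29,3,32,9
n-C15:0,fatty_acid,15,normal,0,1,30,29,3,32,3
i-C16:0,fatty_acid,16,iso,0,1,32,31,3,34,7
n-C16:1,fatty_acid,16,normal,1,1,30,29,3,32,3
n-C16:0,fatty_acid,16,normal,0,1,32,31,3,34,3
i-C17:1,fatty_acid,17,iso,1,1,32,31,3,34,9
a-C17:1,fatty_acid,17,anteiso,1,1,32,31,3,34,9
i-C17:0,fatty_acid,17,iso,0,1,34,33,3,36,9
a-C17:0,fatty_acid,17,anteiso,0,1,34,33,3,36,9
n-C17:0,fatty_acid,17,normal,0,1,34,33,3,36,3
n-C18:1,fatty_acid,18,normal,1,1,34,33,3,36,3
n-C18:0,fatty_acid,18,normal,0,1,36,35,3,38,3
i-C18:0,fatty_acid,18,iso,0,1,36,35,3,38,7
n-C20:0,fatty_acid,20,normal,0,1,40,39,3,42,3
n-C22:0,fatty_acid,22,normal,0,1,44,43,3,46,3
n-C24:0,fatty_acid,24,normal,0,1,48,47,3,50,3
phthalic_acid,diacid_standard,8,normal,0,2,6,4,6,10,NA
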