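"plate_id","row","col","role","compound_id"
"EX01","A",1,"compound","CMPD0001"
"EX01","A",2,"compound","CMPD0002"
"EX01","A",3,"compound","CMPD0003"
"EX01","A",4,"compound","CMPD0004"
"EX01","A",5,"compound","CMPD0005"
"EX01","A",6,"compound","CMPD0006"
"EX01","B",1,"compound","CMPD0007"
"EX01","B",2,"compound","CMPD0008"
"EX01","B",3,"dmso",
"EX01","B",4,"compound","CMPD0009"
"EX01","B",5,"compound","CMPD0010"
"EX01","B",6,"compound","CMPD0011"
"EX01","C",1,"compound","CMPD0012"
"EX01","C",2,"compound","CMPD0013"
"EX01","C",3,"compound","CMPD0014"
"EX01","C",4,"dmso",
"EX01","C",5,"compound","CMPD0015"
"EX01","C",6,"compound","CMPD0016"
"EX01","D",1,"compound","CMPD0017"
"EX01","D",2,"compound","CMPD0018"
"EX01","D",3,"compound","CMPD0019"
"EX01","D",4,"compound","CMPD0020"
"EX01","D",5,"compound","CMPD0021"
"EX01","D",6,"compound","CMPD0022"
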