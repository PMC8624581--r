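gene	synonyms
BBS1	
BBS2	
ARL6	
BBS4	
BBS5	
MKKS	
BBS7	
BBS8	TTC8
BBS9	
BBS10	
TRIM32	
BBS12	
MKS1	
CEP290	
WDPCP	
SDCCA8	
LZTFL1	
BBIP1	BBIP10
IFT27	
IFT172	
C8orf37	
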