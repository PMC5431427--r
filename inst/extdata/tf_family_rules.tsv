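family	required	forbidden
MYB	PF00249	PF01388
bHLH	PF00010	
NAC	PF02365	
TIFY	PF06200	
YABBY	PF04690	
TCP	PF03634	
HB	PF00046	
MADS	PF00319	
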