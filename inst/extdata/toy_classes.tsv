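# Toy motif class table in the ELM "classes" TSV dialect.
Accession	FunctionalSiteName	Regex	#Instances
LIG_Rb_LxCxE	Rb pocket B binding ligand	[LI].C.[DE]	10
TOY_FIW	toy tryptophan site	[FI].W	5
TOY_TRAF	toy TRAF binding	[PSAT].QE	3
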