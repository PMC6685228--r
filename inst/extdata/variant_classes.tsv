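classification	class
Missense_Mutation	nonsynonymous
Nonsense_Mutation	nonsynonymous
Nonstop_Mutation	nonsynonymous
Frame_Shift_Del	nonsynonymous
Frame_Shift_Ins	nonsynonymous
In_Frame_Del	nonsynonymous
In_Frame_Ins	nonsynonymous
Translation_Start_Site	nonsynonymous
Splice_Site	nonsynonymous
Silent	synonymous
Splice_Region	excluded
3'UTR	excluded
5'UTR	excluded
3'Flank	excluded
5'Flank	excluded
Intron	excluded
RNA	excluded
IGR	excluded
Targeted_Region	excluded
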