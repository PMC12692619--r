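allergen	tool	printed	corrected	rationale
Ses i 1	dnastar	5~52	50~52	printed token '5~52' contradicts the published consensus row for this allergen under any k-of-n rule, and the neighbouring tokens (39~49, 56) indicate a dropped digit; read as 50~52
Ses i 7	bepipred	4576~459	457~459	start position 4576 exceeds the protein length and the end precedes it; read as a digit slip for 457~459
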