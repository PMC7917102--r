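# Editable defaults for TAS3 annotation (DNA alphabet, 5'->3').
# mir390: canonical plant mature miR390 (21 nt).
# tasiarf_motif: canonical 21-nt tasiARF sequence used for motif matching.
mir390 = AAGCTCAGGAGGGATAGCGCC
tasiarf_motif = TTCTTGACCTTGTAAGACCCC
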