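# Terminal-atom annotations for the EGFP chromophore: the four
# backbone atoms whose charges the amide-fix scheme constrains.
# Atom types here are the backbone types of the base force field.
# format: name atom_type role terminal_flag
N1   N   chromophore  amide_N
H1   H   chromophore  amide_H
C3   C   chromophore  carbonyl_C
O3   O   chromophore  carbonyl_O
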