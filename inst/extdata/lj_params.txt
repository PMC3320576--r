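# Per-element 12-6 Lennard-Jones parameters, adapted from a standard
# biomolecular set (amide H; sp2/sp3 C; amide N; carbonyl O; thiolate /
# sulfide S; cluster Fe).  sigma in Angstrom, epsilon in kcal/mol.
# Pairs combine by Lorentz-Berthelot rules.
#
# The scale directive multiplies every sigma at load time.  Screening
# discretely sampled conformations against full-size radii rejects nearly
# everything for small strains the sampling cannot relieve; protein-design
# energy functions therefore evaluate steric feasibility with radii scaled
# by 0.9, and the same convention is used here.
#
#   element sigma epsilon
scale 0.9
H   1.069  0.0157
C   3.400  0.0860
N   3.250  0.1700
O   2.960  0.2100
S   3.564  0.2500
FE  2.594  0.0130
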