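# Ideal internal coordinates for the heptapeptide / cluster builder.
# Engh-Huber-style covalent geometry; edit and pass to residue_templates()
# to rebuild every downstream model with different ideals.
#
#   length <atomA>-<atomB> <Angstrom>
#   angle  <atomA>-<atomB>-<atomC> <degrees>
#   param  <name> <value>
#   residue <name> <heavy atoms...>

length N-CA   1.458
length CA-C   1.525
length C-N    1.329
length C-O    1.231
length N-H    1.010
length CA-CB  1.530
length CB-SG  1.808
length SG-FE  2.300
length FE-S   2.280

angle C-N-CA    121.7
angle N-CA-C    111.2
angle CA-C-N    116.2
angle CA-C-O    120.8
angle C-N-H     119.0
angle N-CA-CB   110.5
angle CA-CB-SG  114.4
angle CB-SG-FE  109.5

# Torsion C(i)-N(i)-CA(i)-CB(i) fixing the L configuration at CA
# (measured on refined experimental structures; D would be +122.5).
param cb_torsion -122.5
# Peptide bond torsion CA-C-N-CA; the grid never varies it.
param omega 180
# O-C-N-H torsion across the peptide bond (amide H anti to carbonyl O).
param h_torsion 180
# Fe-Fe distance of the idealized (D2d-compressed) cubane.
param fe_fe 2.73

residue GLY N CA C O
residue ALA N CA C O CB
residue CYS N CA C O CB SG
residue CLU N CA C O CB SG
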