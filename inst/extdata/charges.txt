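# Partial atomic charges (e).  Cluster and cysteine Sgamma values are the
# modified set for an oxidized [Fe4S4]2+ core bound to three cysteines with
# a net complex charge of -1; backbone values are a standard amide-dipole
# set, with CA and CB(CYS) balancing so each residue unit is integral.
# Keys: <residue>.<atom> with residue "*" as wildcard; "NT" is the
# N-terminal nitrogen (no amide H modeled there, so it absorbs the H
# charge).
#
#   key charge
*.N    -0.4157
*.NT   -0.1438
*.H     0.2719
*.CA    0.1144
*.C     0.5973
*.O    -0.5679
CYS.CB  0.1421
CLU.CB  0.1421
ALA.CB  0.0000
*.SG   -0.6042
SF4.FE  0.6518
SF4.S  -0.5552
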