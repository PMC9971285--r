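name	formula	delta_mass	site	classification	neutral_loss	diagnostic_ion_mz
OPP_full	C27H35N11O4	577.2873	peptide-C-terminus	variable	C7H9N5	164.0931
OPP_purine_loss	C20H26N6O4	414.2016	peptide-C-terminus	variable		
Carbamidomethyl	C2H3NO	57.0215	residue-C	fixed		
Oxidation	O	15.9949	residue-M	variable		
Acetyl	C2H2O	42.0106	protein-N-terminus	variable		
Met_loss	-C5H9NOS	-131.0405	protein-N-terminus	variable		
Gln_pyroGlu	-H3N	-17.0265	peptide-N-terminus-Q	variable		
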