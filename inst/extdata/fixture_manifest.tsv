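# fixture manifest: synthetic sequence stand-ins packaged with jiptandem
# The JIP3/JIP4 records are constructed, not transcribed: they honour the
# published residue-level description of the region (named hydrophobic-core
# and interface residues, the 72-ENQEHE-77 linker, heptad register and a/d
# core of the LZI, region masses with the GSH expression-tag remnant, and
# the RH1 ungapped identity between the homologs) but intervening residues
# are invented. Reference database entries for the real sequences:
# JIP3 human NP_055948.2; JIP4 human NP_001123999.1; JIP3 mouse NP_038959.2.
file	md5
jip_nterm_synthetic.fasta	b638900d1c8a79a7544f44b8362f9b2e
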