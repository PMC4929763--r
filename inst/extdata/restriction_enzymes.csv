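# Default restriction-enzyme table: common commercial 6-cutters.
# This list is a user-replaceable default, not an authoritative catalog.
# Format: name,IUPAC recognition site. Lines starting with '#' are ignored.
EcoRI,GAATTC
BamHI,GGATCC
HindIII,AAGCTT
XhoI,CTCGAG
NdeI,CATATG
SpeI,ACTAGT
PstI,CTGCAG
SalI,GTCGAC
NcoI,CCATGG
KpnI,GGTACC
SacI,GAGCTC
XbaI,TCTAGA
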