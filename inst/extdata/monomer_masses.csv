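name,kind,molar_mass
Morph,monomer,141.17
Nipam,monomer,113.16
Dodecyl,monomer,239.40
CPDT,end_group,345.6
AIBN,end_group,68.1
V70,end_group,140.2
VA044,end_group,111.2
ACVA,end_group,126.1
none,end_group,0
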