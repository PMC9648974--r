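# Synthetic stand-in annotation fixture: a small curated list of canonical
# mouse mitochondrial gene symbols (ETC subunits, assembly factors, matrix
# enzymes). Not a copy of any database; matching is case-insensitive.
Ndufa9
Ndufs1
Ndufs2
Ndufs4
Ndufv1
Ndufv2
Ndufb8
Sdha
Sdhb
Sdhc
Sdhd
Uqcrc1
Uqcrc2
Uqcrfs1
Cyc1
Cox4i1
Cox5a
Cox5b
Cox6b1
Cox7a2
Mtco1
Mtco2
Atp5a1
Atp5b
Atp5o
Etfa
Etfb
Etfdh
Cs
Aco2
Idh2
Idh3a
Ogdh
Sucla2
Suclg1
Fh1
Mdh2
Cpt1a
Cpt2
Hadha
Hadhb
Acadm
Acadl
Acadvl
Pdha1
Pdhb
Dld
Got2
Glud1
Hmgcs2
Bdh1
Pcx
Sod2
Tfam
Polg
Vdac1
Slc25a4
Timm23
Tomm20
Hspd1
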