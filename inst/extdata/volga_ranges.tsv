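# Species range table for the Middle Volga audit fixture (focal region VLG).
# Curated from the range statements accompanying the audit: conflicting species
# known only from remote regions (Mongolia, Altai, the Balkans, Iran, North
# Africa, Western Europe, Central/East Asia) versus species present or probably
# present in the Volga-Ural region. Synthetic curation artifact, not a published
# table. Region codes: VLG Volga-Ural, W-EU Western Europe, E-EU Eastern Europe,
# BLK Balkans, CAU Caucasus, IRN Iran, C-AS Central Asia, E-AS East Asia,
# N-AF North Africa, ALT Altai, MNG Mongolia.
species	regions
Apatura metis	VLG;E-EU
Aphantopus bieti	E-AS
Callophrys chalybeitincta	VLG;CAU
Novosatsuma collosa	E-AS
Coenonympha leander	VLG;E-EU
Coenonympha orientalis	BLK
Colias crocea	VLG;W-EU;E-EU
Colias marnoana	N-AF
Colias poliographus	E-AS
Colias caucasica	BLK
Cupido staudingeri	IRN
Davidina dzhulukuli	ALT
Davidina lederi	MNG
Iphiclides feistahameli	W-EU
Melitaea sibina	C-AS
Melitaea ornata	VLG
Papilio saharae	N-AF
Pyrgus malvoides	W-EU
Apatura ilia	VLG;E-EU;W-EU
Colias erate	VLG;C-AS
Colias myrmidone	VLG;E-EU
Davidina tarpeia	VLG;ALT;MNG
Iphiclides podalirius	VLG;W-EU;E-EU
Melitaea phoebe	VLG;E-EU
Papilio machaon	VLG;W-EU;E-EU;C-AS
Pyrgus malvae	VLG;W-EU;E-EU
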