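family	category	note
GH13	alpha_glucan	alpha-glucosidase/amylase (starch, pullulan)
GH77	alpha_glucan	4-alpha-glucanotransferase
GH31	alpha_glucan	alpha-glucosidase
GH15	alpha_glucan	glucoamylase
GH37	alpha_glucan	trehalase
GH97	alpha_glucan	glucoamylase/alpha-glucosidase
GH65	alpha_glucan	maltose phosphorylase
CBM48	alpha_glucan	glycogen/starch binding
GH16	beta_glucan	endo-beta-1,3-glucanase (laminarinase)
GH17	beta_glucan	endo-beta-1,3-glucanase
GH30	beta_glucan	beta-1,6-side-chain glucosidase
GH1	beta_glucan	beta-glucosidase (oligo beta-glucan)
GH3	beta_glucan	beta-glucosidase (oligo beta-glucan)
GH23	N_glycan	lysozyme/peptidoglycan lytic transglycosylase
GH103	N_glycan	peptidoglycan lytic transglycosylase
GH73	N_glycan	peptidoglycan hydrolase
GH24	N_glycan	lysozyme
GH108	N_glycan	lysozyme
GH18	N_glycan	chitinase
GH20	N_glycan	beta-N-acetylglucosaminidase
GH109	N_glycan	N-acetylhexosaminidase
GH33	N_glycan	sialidase (glycoconjugates)
AA10	N_glycan	lytic polysaccharide monooxygenase on chitin
GH43	cellulose_hemicellulose	beta-xylosidase/arabinofuranosidase
GH2	cellulose_hemicellulose	arabinosidase/beta-galactosidase
GH5	cellulose_hemicellulose	cellulase/endo-xylanase
CE1	cellulose_hemicellulose	acetyl-xylan esterase
GH130	beta_mannoside	beta-1,4-mannooligosaccharide phosphorylase
GH26	beta_mannoside	beta-mannanase
AA2	lignin	peroxidase
AA3	lignin	GMC oxidoreductase
AA6	lignin	benzoquinone reductase (Fenton support)
GH29	fucose_SP	alpha-L-fucosidase
GH95	fucose_SP	alpha-L-fucosidase
CBM47	fucose_SP	fucose binding
GH78	rhamnose_SP	alpha-L-rhamnosidase
GH106	rhamnose_SP	alpha-L-rhamnosidase
GH145	rhamnose_SP	rhamnogalacturonan hydrolase
CBM67	rhamnose_SP	rhamnose binding
PL1	pectin	pectate lyase
GH28	pectin	polygalacturonase
GH105	pectin	unsaturated glucuronyl/galacturonyl hydrolase
CE8	pectin	pectinesterase
CE12	pectin	pectin acetylesterase
PL6	alginate	alginate lyase
PL7	alginate	alginate lyase
PL17	alginate	oligo-alginate lyase
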