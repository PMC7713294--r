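species,epsilon_M_cm,wavelength_nm,surrogate_of
phytoene,68000,286,
phytofluene,73000,348,
zeta_carotene,138000,400,
neurosporene,157000,440,
lycopene,185000,470,
didehydrolycopene,160000,490,
tetradehydrolycopene,,490,didehydrolycopene
beta_zeacarotene,124000,428,
dihydro_beta_carotene,125000,430,
gamma_carotene,160000,462,
beta_carotene,139000,450,
torulene,160000,484,
dehydro_beta_carotene,,428,beta_zeacarotene
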