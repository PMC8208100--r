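ion,z,lambda,note
K,1,73.50,limiting equivalent conductivity at 25 C (CRC Handbook)
Na,1,50.11,CRC Handbook
Cl,-1,76.35,CRC Handbook
OH,-1,198.0,CRC Handbook
HCO3,-1,44.50,CRC Handbook
H2PO4,-1,33.00,CRC Handbook
Mg,2,53.06,per equivalent (1/2 Mg2+)
Ca,2,59.50,per equivalent (1/2 Ca2+)
gluconate,-1,24.40,electrophysiology junction-potential literature (Barry & Lynch compilation)
HEPES,-1,22.05,junction-potential literature
EGTA,-2,24.00,junction-potential literature (per equivalent)
ATP,-2,24.00,dominant MgATP2- species at pH 7.3 (per equivalent)
GTP,-3,24.00,junction-potential literature (per equivalent)
SO4,-2,80.00,per equivalent (1/2 SO4 2-)
acetate,-1,40.90,CRC Handbook
Cs,1,77.20,CRC Handbook
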