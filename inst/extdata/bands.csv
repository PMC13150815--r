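component,center,fwhm,height
urea,1626,22,0.50
urea,1599,20,0.45
urea,1466,40,0.35
urea,1160,60,0.10
creatinine,1690,30,0.055
creatinine,1620,35,0.060
creatinine,1490,35,0.085
creatinine,1423,30,0.050
creatinine,1305,40,0.040
albumin,1652,60,0.110
albumin,1548,55,0.075
albumin,1404,50,0.020
albumin,1300,60,0.012
glucose,1035,40,0.30
glucose,1080,40,0.25
glucose,1150,45,0.12
glucose,992,30,0.10
MgSO4,1100,55,0.12
MgSO4,983,25,0.02
Na2SO4,1100,55,0.28
Na2SO4,983,25,0.05
NaH2PO4,1080,50,0.25
NaH2PO4,1160,45,0.10
NaH2PO4,940,40,0.08
Na3citrate,1580,50,0.10
Na3citrate,1390,45,0.08
Na3citrate,1280,40,0.03
NH4Cl,1450,60,0.10
NaHCO3,1360,50,0.020
NaHCO3,1630,45,0.010
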