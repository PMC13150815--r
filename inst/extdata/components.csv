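name,mol_class,standard_conc,cal_min,cal_max,ref_min,ref_max
CaCl2,non_absorbing_salt,3180,12.23,917.09,24.46,611.39
creatinine,low_mw,12000,267.11,2348.8,400.67,1957.33
KCl,non_absorbing_salt,23000,563.28,4592.36,844.91,3826.97
MgSO4,low_mw,11000,229.81,2181.83,344.71,1818.19
Na3citrate,low_mw,7200,150.36,1458.56,225.54,1215.47
NaCl,non_absorbing_salt,52000,1064.91,10612.7,1597.36,8843.92
NaH2PO4,low_mw,36000,1386.72,6240.24,2080.08,5200.2
Na2SO4,low_mw,26000,441.9,5340.7,662.85,4450.59
urea,low_mw,150000,4444,28000,6666,23333.33
NH4Cl,low_mw,12700,356.67,2396.8,535,1997.33
albumin,protein,15000,0,300,30,3000
glucose,low_mw,100000,0,750,250,20000
NaHCO3,low_mw,2300,28,514.12,33.6,428.44
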