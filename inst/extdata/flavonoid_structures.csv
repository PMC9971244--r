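name,smiles,n_heavy,d_reproducible,zeta_reproducible,note
Kojic acid,OCC1=CC(=O)C(O)=CO1,10,TRUE,FALSE,tabulated internal sum 23.8333 vs computed 24.8333; no pyranone positional isomer reproduces it
Chrysin,O=c1cc(-c2ccccc2)oc2cc(O)cc(O)c12,19,TRUE,TRUE,
Shikonin,CC(C)=CCC(O)C1=CC(=O)c2c(O)ccc(O)c2C1=O,21,TRUE,TRUE,
Baicalein,O=c1cc(-c2ccccc2)oc2cc(O)c(O)c(O)c12,20,TRUE,TRUE,
Galangin,O=c1c(O)c(-c2ccccc2)oc2cc(O)cc(O)c12,20,TRUE,TRUE,
Dihydromyricetin,OC1C(Oc2cc(O)cc(O)c2C1=O)c1cc(O)c(O)c(O)c1,23,TRUE,TRUE,
Naphthazarin,O=C1C=CC(=O)c2c(O)ccc(O)c12,14,TRUE,TRUE,
Xanthoxylin,CC(=O)c1c(O)cc(OC)cc1OC,14,TRUE,FALSE,tabulated internal sum 29.0 vs computed 29.5; no acetophenone positional isomer reproduces it
Tropolone,OC1=CC=CC=CC1=O,9,TRUE,TRUE,
Morin,O=c1c(O)c(-c2ccc(O)cc2O)oc2cc(O)cc(O)c12,22,TRUE,TRUE,
Quercetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12,22,TRUE,TRUE,canonical zeta 0.177341598 = (515/6)/484
Quercetin-3-rutinoside,CC1OC(OCC2OC(Oc3c(-c4ccc(O)c(O)c4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O,43,FALSE,FALSE,tabulated descriptors duplicate quercetin's; true 43-heavy-atom rutinoside differs
Taxfolin,OC1C(Oc2cc(O)cc(O)c2C1=O)c1ccc(O)c(O)c1,22,TRUE,TRUE,also Taxifolin (dihydroquercetin); same hydrogen-suppressed graph as quercetin; tabulated zeta 0.177341529 = 85.8333/484 from the 4-dp-rounded numerator
Rhamnetin,COc1cc(O)c2c(=O)c(O)c(-c3ccc(O)c(O)c3)oc2c1,23,TRUE,TRUE,
Dihydroquercetin-4'-methylether,COc1ccc(C2Oc3cc(O)cc(O)c3C(=O)C2O)cc1O,23,FALSE,TRUE,tabulated external sum 205 is odd; the external numerator is always even (computed 206)
Tamarixetin,COc1ccc(-c2oc3cc(O)cc(O)c3c(=O)c2O)cc1O,23,TRUE,FALSE,tabulated internal sum 102.5 vs computed 99.0; no methyl-ether positional isomer reproduces it
"Dihydroquercetin-7,4'-dimethylether",COc1ccc(C2Oc3cc(OC)cc(O)c3C(=O)C2O)cc1O,24,FALSE,TRUE,tabulated external sum 215 is odd; the external numerator is always even (computed 216)
Luteolin,O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12,21,TRUE,TRUE,
Luteolin-7-methyl ether,COc1cc(O)c2c(=O)cc(-c3ccc(O)c(O)c3)oc2c1,22,TRUE,FALSE,tabulated internal sum 98.0 vs computed 100.5; no methyl-ether positional isomer reproduces it
"5,7,3',5'-Tetrahydroxyflavanone",O=C1CC(c2cc(O)cc(O)c2)Oc2cc(O)cc(O)c21,21,TRUE,TRUE,
Blumeatin,COc1cc(O)c2C(=O)CC(c3cc(O)cc(O)c3)Oc2c1,22,FALSE,TRUE,tabulated external sum 143 is odd; the external numerator is always even (computed 144)
Apigenin,O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12,20,TRUE,TRUE,
Fisetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)ccc12,21,TRUE,TRUE,
Rosmarinic acid,OC(=O)C(Cc1ccc(O)c(O)c1)OC(=O)C=Cc1ccc(O)c(O)c1,26,FALSE,TRUE,tabulated external sum 355 is odd; the external numerator is always even (computed 356)
"3,7,4'-Trihydroxyflavone",O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)ccc12,20,TRUE,FALSE,tabulated zeta 0.2352 implies internal sum 94.08 which no sum of sixths can equal; computed 94.0
Isoeugenol,CC=Cc1ccc(O)c(OC)c1,12,TRUE,TRUE,
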