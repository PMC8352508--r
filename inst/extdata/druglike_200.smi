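CC(=O)Oc1ccccc1C(=O)O aspirin
CC(=O)Nc1ccc(O)cc1 paracetamol
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
OC(=O)c1ccccc1O salicylic_acid
Clc1ccccc1 chlorobenzene
Nc1ccc(cc1)S(N)(=O)=O sulfanilamide
CC1=CC(=O)C=CC1=O methylquinone
OCC1OC(O)C(O)C(O)C1O glucose_like
CN1CCC23c4c5ccc(O)c4OC2C(=O)CCC3C1C5 morphinan_like
NC(Cc1ccccc1)C(=O)O phenylalanine
NC(Cc1c[nH]c2ccccc12)C(=O)O tryptophan
NC(CO)C(=O)O serine
CC(N)C(=O)O alanine
NCCc1c[nH]c2ccccc12 tryptamine
NCCc1ccc(O)c(O)c1 dopamine
CNCC(O)c1ccc(O)c(O)c1 epinephrine_like
CC(CN)O aminopropanol
c1ccc2[nH]ccc2c1 indole
c1ccc2ncccc2c1 quinoline
c1ccc2ccccc2c1 naphthalene
c1ccoc1 furan
c1ccsc1 thiophene
c1cc[nH]c1 pyrrole
c1ccncc1 pyridine
c1cnc[nH]1 imidazole
c1cncnc1 pyrimidine
Cc1ccccc1 toluene
Cc1ccccc1C xylene
COc1ccccc1 anisole
Oc1ccccc1 phenol
Nc1ccccc1 aniline
CC(=O)c1ccccc1 acetophenone
OC(=O)c1ccccc1 benzoic_acid
NC(=O)c1ccccc1 benzamide
N#Cc1ccccc1 benzonitrile
O=Cc1ccccc1 benzaldehyde
OCc1ccccc1 benzyl_alcohol
CCOC(=O)c1ccccc1 ethyl_benzoate
CN(C)c1ccccc1 dimethylaniline
Fc1ccccc1 fluorobenzene
Brc1ccccc1 bromobenzene
Ic1ccccc1 iodobenzene
CCN(CC)CC triethylamine
CCOCC diethyl_ether
CCCCCC hexane
CCCCCCO hexanol
CC(C)O isopropanol
CC(C)=O acetone
CCC(=O)O propionic_acid
CC(=O)OC ethyl_acetate_like
CC#N acetonitrile
CS(=O)C dmso_like
O=S(=O)(O)c1ccccc1 benzenesulfonic_acid
Clc1ccc(Cl)cc1 dichlorobenzene
Oc1ccc(Cl)cc1 chlorophenol
COc1ccc(CCN)cc1 methoxyphenethylamine
CN1CCCC1 methylpyrrolidine
C1CCNCC1 piperidine
C1CCOC1 thf
C1CCOCC1 oxane
C1CCNC1 pyrrolidine
O1CCOCC1 dioxane
C1CCCCC1 cyclohexane
C1CCCC1 cyclopentane
C1CC1 cyclopropane
OC1CCCCC1 cyclohexanol
O=C1CCCCC1 cyclohexanone
NC1CCCCC1 cyclohexylamine
C1CN(CCN1)C piperazine_methyl
c1ccc(cc1)c1ccccc1 biphenyl
c1ccc(cc1)Oc1ccccc1 diphenyl_ether
c1ccc(cc1)Cc1ccccc1 diphenylmethane
O=C(Nc1ccccc1)c1ccccc1 benzanilide
CC(C)NCC(O)COc1ccccc1 propranolol_frag
CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1 atropine_like
CCN(CC)C(=O)C1CN(C)C2CC3=CNc4cccc(C2=C1)c34 lsd_like
CN1CCC(CC1)=C1c2ccccc2CCc2ccccc12 amitriptyline_like
OC(=O)C1CCCCN1 pipecolic_acid
NC(=O)C1CCCN1 prolinamide
OC(c1ccccc1)c1ccccc1 benzhydrol
O=C(c1ccccc1)c1ccccc1 benzophenone
CC(C)(C)c1ccccc1 tertbutylbenzene
CC(C)(C)OC(=O)N tboc_amide
CCOC(=O)CC ester2
CCCC(=O)OCC ester3
CNC(=O)Oc1ccccc1 carbamate
COC(=O)c1ccccc1O methyl_salicylate
Oc1ccc2ccccc2c1 naphthol
Nc1ccc2ccccc2c1 naphthylamine
OC(=O)Cc1ccccc1 phenylacetic_acid
OC(=O)CCc1ccccc1 phenylpropionic_acid
NCCc1ccccc1 phenethylamine
NCc1ccccc1 benzylamine
CNCc1ccccc1 methylbenzylamine
OCCc1ccccc1 phenethanol
COc1cc2c(cc1OC)CCNC2 heliamine_like
CN1CCc2cc(OC)c(OC)cc2C1 tetrahydroisoquinoline
O=c1cc[nH]c(=O)[nH]1 uracil
Cc1c[nH]c(=O)[nH]c1=O thymine
Nc1cc[nH]c(=O)n1 cytosine_like
c1ncc2[nH]cnc2n1 purine
Nc1ncnc2[nH]cnc12 adenine
NC(=O)c1cccnc1 nicotinamide
OC(=O)c1cccnc1 nicotinic_acid
CN1CCCC1c1cccnc1 nicotine
Cn1cccc1 methylpyrrole
Cc1occc1 methylfuran
Cc1sccc1 methylthiophene
CCc1ccccn1 ethylpyridine
Clc1cccnc1 chloropyridine
Nc1ccccn1 aminopyridine
Oc1ccccn1 hydroxypyridine
COc1ccccn1 methoxypyridine
O=C(O)c1ccc(Cl)cc1 chlorobenzoic_acid
O=C(O)c1ccc(N)cc1 aminobenzoic_acid
O=C(O)c1ccc(O)cc1 hydroxybenzoic_acid
CC(=O)Nc1ccccc1 acetanilide
O=C(Cl)c1ccccc1 benzoyl_chloride
CC(Cl)c1ccccc1 chloroethylbenzene
ClCc1ccccc1 benzyl_chloride
FC(F)(F)c1ccccc1 trifluoromethylbenzene
FC(F)(F)c1ccc(N)cc1 tfm_aniline
N#Cc1ccc(O)cc1 hydroxybenzonitrile
O=[N+]([O-])c1ccccc1 nitrobenzene
O=[N+]([O-])c1ccc(N)cc1 nitroaniline
O=[N+]([O-])c1ccc(O)cc1 nitrophenol
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
CC(C)NCC(O)c1ccc(O)c(O)c1 isoprenaline
COC(=O)C1C2CCC(CC1OC(=O)c1ccccc1)N2C cocaine
CN1CCC(CC1)Oc1ccccc1 phenoxypiperidine
O=C1NC(=O)NC(=O)C1(CC)CC barbital
O=C1NC(=O)NC(=O)C1(CC)c1ccccc1 phenobarbital_like
Clc1ccc2nc(NC3CCCCC3)[nH]c2c1 benzimidazole_drug
CN(C)CCCN1c2ccccc2Sc2ccccc21 promazine
CN(C)CCCN1c2ccccc2CCc2ccccc21 imipramine_like
Clc1ccccc1C1=NCC(=O)Nc2ccc(cc12)[N+](=O)[O-] nitro_benzodiazepine_like
OCC(O)C(O)C(O)C(O)CO sorbitol
OCC(O)CO glycerol
OCCO ethylene_glycol
OCCN ethanolamine
NCCN ethylenediamine
NCCCCN putrescine
NCCCCCN cadaverine
OC(=O)CCC(=O)O succinic_acid
OC(=O)CC(=O)O malonic_acid
OC(=O)C(O)C(O)C(=O)O tartaric_acid
OC(=O)CC(O)(CC(=O)O)C(=O)O citric_acid
CC(O)C(=O)O lactic_acid
OCC(=O)O glycolic_acid
NCC(=O)O glycine
CC(C)CC(N)C(=O)O leucine
CC(C)C(N)C(=O)O valine
NC(CCC(=O)O)C(=O)O glutamic_acid
NC(CC(=O)O)C(=O)O aspartic_acid
NC(CCCCN)C(=O)O lysine
CSCCC(N)C(=O)O methionine
NC(CS)C(=O)O cysteine
OC(=O)c1cc(O)c(O)c(O)c1 gallic_acid
COc1cc(C=CC(=O)O)ccc1O ferulic_acid
Oc1ccc(C=CC(=O)O)cc1 coumaric_acid
O=c1ccc2ccccc2o1 coumarin
O=c1cc(-c2ccccc2)oc2ccccc12 flavone
Oc1cc(O)c2c(c1)oc(-c1ccc(O)cc1)cc2=O apigenin_like
COc1ccc(C(=O)CC(=O)c2ccc(OC)cc2)cc1 curcumin_frag
CC1=CC(=O)CC(C)(C)C1 isophorone
CC1CCC(C(C)C)C(O)C1 menthol
CC1=CCC(CC1)C(C)=C limonene_like
CC(=O)CCC1=CC(=O)CCC1 ketone_terpene
O=C1CCCN1 pyrrolidinone
O=C1CCCCN1 piperidinone
O=C1OCCC1 butyrolactone
O=C1OC(=O)CC1 succinic_anhydride_like
CN(C)C=O dmf
CC(=O)N(C)C dma
CCOC(=O)N urethane
NC(=O)N urea
CNC(=O)NC methylurea
NC(=N)N guanidine
CC(=O)NCC(=O)O acetylglycine
CC(C)(C)OC(=O)NCC(=O)O boc_glycine
O=C(O)CN1CCN(CC(=O)O)CC1 edta_frag
Clc1cc2c(cc1Cl)N(CCCN(C)C)c1ccccc1S2 chlorpromazine_like
COc1ccc2cc(CCN)c(=O)[nH]c2c1 carbostyril_like
CCOc1ccc(NC(C)=O)cc1 phenacetin
CC(=O)Oc1ccc2ccccc2c1 naphthyl_acetate
CC(C)Oc1ccccc1 isopropoxybenzene
CCCCc1ccccc1 butylbenzene
CCCCCCCC(=O)O octanoic_acid
CCCCCCCCO octanol
CCCCCC=O hexanal
CC=CC=O crotonaldehyde
C=CC(=O)O acrylic_acid
C=CC#N acrylonitrile
CC=C(C)C(=O)O tiglic_acid
CC(=CCO)C prenol
CC(C)=CCCC(C)=CCO geraniol
CO methanol
CCO ethanol
CCCO propanol
CCCCO butanol
CC(=O)O acetic_acid
OC=O formic_acid
CC(=O)OCC ethyl_acetate
CN methylamine
CCN ethylamine
CCCN propylamine
CNC dimethylamine
CCNCC diethylamine
CCl chloroethane_frag
CCCl chloroethane
CCC propane
CCCC butane
CC(=O)N acetamide
CCC(=O)N propionamide
CCS ethanethiol
CCCS propanethiol
CC=O acetaldehyde
CCC=O propanal
CC(C)C isobutane
CC(C)CO isobutanol
CCOC ethylmethylether
CCCOC methylpropylether
CCC(C)O butanol2
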