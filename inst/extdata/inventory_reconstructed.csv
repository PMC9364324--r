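name,category,smiles,source_reviews
N-formylated peptides,MAMPs,,1
lipoteichoic acid,MAMPs,,2
peptidoglycan,MAMPs,,3
lipopeptides,MAMPs,,1
lipopolysaccharides,MAMPs,,2;9
glucans,MAMPs,,3
mannans,MAMPs,,1
chitins,MAMPs,,2
capsular polysaccharides,MAMPs,,3
muramyl dipeptide,MAMPs,,1;7
teichoic acid,MAMPs,,4
exopolysaccharides,MAMPs,,5;8
zymosan,MAMPs,,4;8
curdlan,MAMPs,,5
dextran,MAMPs,,4
levan,MAMPs,,4
trehalose dimycolate,MAMPs,,8
arabinogalactan,MAMPs,,5
lipomannan,MAMPs,,9
lipoarabinomannan,MAMPs,,10
CpG DNA,MAMPs,,7
N-formylmethionyl-leucyl-phenylalanine,MAMPs,,5
porins,MAMPs,,6
menaquinone-4,vitamins,,2
cobalamin,vitamins,,3
biotin,vitamins,OC(=O)CCCC[C@@H]1SC[C@@H]2NC(=O)N[C@H]12,1
folate,vitamins,Nc1nc2ncc(CNc3ccc(C(=O)NC(CCC(O)=O)C(O)=O)cc3)nc2c(=O)[nH]1,2
thiamine,vitamins,Cc1ncc(C[n+]2csc(CCO)c2C)c(N)n1,3;5
riboflavin,vitamins,Cc1cc2nc3c(=O)[nH]c(=O)n(CC(O)C(O)C(O)CO)c3nc2cc1C,1
pyridoxine,vitamins,Cc1ncc(CO)c(CO)c1O,2
niacin,vitamins,OC(=O)c1cccnc1,3
pantothenic acid,vitamins,CC(C)(CO)C(O)C(=O)NCCC(O)=O,1
"5,10-methenyltetrahydropteroylglutamate",vitamins,,4
polyglutamylated folate,vitamins,,5
acetic acid,SCFAs,CC(O)=O,2;10
propionic acid,SCFAs,CCC(O)=O,3
butyric acid,SCFAs,CCCC(O)=O,1
isobutyric acid,SCFAs,CC(C)C(O)=O,2
2-methylbutyric acid,SCFAs,CCC(C)C(O)=O,3
valeric acid,SCFAs,CCCCC(O)=O,1;8
isovaleric acid,SCFAs,CC(C)CC(O)=O,2
hexanoic acid,SCFAs,CCCCCC(O)=O,3
cholic acid,PBAs,,1
chenodeoxycholic acid,PBAs,,2
12-dehydrocholate,SBAs,,3;6
7-ketodeoxycholic acid,SBAs,,1
7-dehydrochenodeoxycholate,SBAs,,2
3-dehydrocholic acid,SBAs,,3
3-dehydrochenodeoxycholic acid,SBAs,,1
isocholic acid,SBAs,,2;4
isochenodeoxycholic acid,SBAs,,3
lithocholic acid,SBAs,,1
deoxycholic acid,SBAs,,2
allolithocholic acid,SBAs,,3
allodeoxycholic acid,SBAs,,1;9
ursocholic acid,SBAs,,2
ursodeoxycholic acid,SBAs,,3
hyocholic acid,SBAs,,1
hyodeoxycholic acid,SBAs,,2
7-oxolithocholic acid,SBAs,,3;7
taurocholic acid,CBAs,,1
glycocholic acid,CBAs,,2
taurohyocholic acid,CBAs,,3
taurochenodeoxycholic acid,CBAs,,1
glycochenodeoxycholic acid,CBAs,,2;5
glycodeoxycholic acid,CBAs,,3
taurodeoxycholic acid,CBAs,,1
N-acetyltryptophan,tryptophan,CC(=O)NC(Cc1c[nH]c2ccccc12)C(O)=O,2
indoleacetic acid,tryptophan,OC(=O)Cc1c[nH]c2ccccc12,3
indoleacetylglycine,tryptophan,OC(=O)CNC(=O)Cc1c[nH]c2ccccc12,1;10
indole,tryptophan,c1ccc2[nH]ccc2c1,2
indoxyl sulfate,tryptophan,OS(=O)(=O)Oc1c[nH]c2ccccc12,3
indole-3-propionic acid,tryptophan,OC(=O)CCc1c[nH]c2ccccc12,1
melatonin,tryptophan,CC(=O)NCCc1c[nH]c2ccc(OC)cc12,2
melatonin 6-sulfate,tryptophan,,5;8
5-hydroxyindole,tryptophan,Oc1ccc2[nH]ccc2c1,3;8
5-hydroxytryptamine,tryptophan;neurotransmitters,NCCc1c[nH]c2ccc(O)cc12,1
indoleacrylic acid,tryptophan,OC(=O)/C=C/c1c[nH]c2ccccc12,2
indoleethanol,tryptophan,OCCc1c[nH]c2ccccc12,3
tryptamine,tryptophan,NCCc1c[nH]c2ccccc12,1
3-methylindole,tryptophan,Cc1c[nH]c2ccccc12,2;6
indole-3-carboxylate,tryptophan,OC(=O)c1c[nH]c2ccccc12,3
indolelactate,tryptophan,OC(Cc1c[nH]c2ccccc12)C(O)=O,5
acetylcholine,tryptophan;neurotransmitters,CC(=O)OCC[N+](C)(C)C,1
putrescine,polyamines,NCCCCN,2
cadaverine,polyamines,NCCCCCN,3
spermidine,polyamines,NCCCCNCCCN,1;4
spermine,polyamines,NCCCNCCCCNCCCN,2
methylamine,choline,CN,3
dimethylamine,choline,CNC,1
trimethylamine,choline,CN(C)C,2
trimethylamine-N-oxide,choline,C[N+](C)(C)[O-],3;9
dimethylglycine,choline,CN(C)CC(O)=O,1
betaine,choline,C[N+](C)(C)CC([O-])=O,2
noradrenaline,neurotransmitters,NCC(O)c1ccc(O)c(O)c1,3
gamma-aminobutyric acid,neurotransmitters,NCCCC(O)=O,1
dopamine,neurotransmitters,NCCc1ccc(O)c(O)c1,2;7
histamine,neurotransmitters,NCCc1c[nH]cn1,3
benzoate,phenolic,OC(=O)c1ccccc1,1
hippurate,phenolic,OC(=O)CNC(=O)c1ccccc1,2
phenylacetate,phenolic,OC(=O)Cc1ccccc1,3
phenylpropionate,phenolic,OC(=O)CCc1ccccc1,1;5
3-hydroxycinnamate,phenolic,OC(=O)/C=C/c1cccc(O)c1,2
2-hydroxyhippurate,phenolic,OC(=O)CNC(=O)c1ccccc1O,3
3-hydroxyhippurate,phenolic,OC(=O)CNC(=O)c1cccc(O)c1,1
2-hydroxybenzoate,phenolic,OC(=O)c1ccccc1O,2
3-hydroxybenzoate,phenolic,OC(=O)c1cccc(O)c1,3;10
4-hydroxybenzoate,phenolic,OC(=O)c1ccc(O)cc1,1
4-hydroxyphenylacetate,phenolic,OC(=O)Cc1ccc(O)cc1,2
3-hydroxyphenylpropionate,phenolic,OC(=O)CCc1cccc(O)c1,3
4-hydroxyphenylpropionate,phenolic,OC(=O)CCc1ccc(O)cc1,1
"3,4-dihydroxyphenylpropionate",phenolic,OC(=O)CCc1ccc(O)c(O)c1,2;8
4-cresol,phenolic,Cc1ccc(O)cc1,3
4-cresyl sulfate,phenolic,Cc1ccc(OS(O)(=O)=O)cc1,1
4-cresyl glucuronide,phenolic,,2
phenylacetylglutamine,phenolic,NC(=O)CCC(NC(=O)Cc1ccccc1)C(O)=O,3
phenylacetylglycine,phenolic,OC(=O)CNC(=O)Cc1ccccc1,1;6
phenylpropionylglycine,phenolic,OC(=O)CNC(=O)CCc1ccccc1,2
cinnamoylglycine,phenolic,OC(=O)CNC(=O)/C=C/c1ccccc1,3
4-ethylphenyl sulfate,phenolic,CCc1ccc(OS(O)(=O)=O)cc1,1
phenol,phenolic,Oc1ccccc1,2
s-equol,phenolic,Oc1ccc(cc1)C1COc2cc(O)ccc2C1,3;4
sphingomyelin,lipid,,1
cholesterol,lipid,,2
phosphatidylcholine,lipid,,3
phosphoethanolamines,lipid,,1
triglycerides,lipid,,2;9
sphingolipids,lipid,,3
linoleic acid,lipid,CCCCC/C=C\C/C=C\CCCCCCCC(O)=O,1
caproic acid,lipid,CCCCCC(O)=O,2
endocannabinoids,lipid,,3
ceramides,lipid,,5;8
lysophosphatidylcholine,lipid,,4
oleic acid,lipid,CCCCCCCC/C=C\CCCCCCCC(O)=O,5
conjugated linoleic acid,lipid,,4;8
microbial anti-inflammatory molecule,proteins,,1;7
bacteriocins,proteins,,2
alpha-hemolysin,proteins,,3
Amuc_1100,proteins,,1
serine protease,proteins,,2
serpins,proteins,,3;5
lactocepin,proteins,,1
flagellin,proteins,,4;8
invasin,proteins,,5
p40 protein,proteins,,4
p75 protein,proteins,,7
elastase,proteins,,6
methanol,other,CO,2
ethanol,other,CCO,3
formate,other,OC=O,1
succinate,other,OC(=O)CCC(O)=O,2;10
lysine,other,NCCCCC(N)C(O)=O,3
glucose,other,OCC1OC(O)C(O)C(O)C1O,1
urea,other,NC(N)=O,2
alpha-ketoisovalerate,other,CC(C)C(=O)C(O)=O,3
creatine,other,CN(CC(O)=O)C(N)=N,1;8
creatinine,other,CN1CC(=O)NC1=N,2
imidazole propionate,other,OC(=O)CCc1cnc[nH]1,3
hydrogen peroxide,other,OO,1
reactive aldehydes,other,,2
quorum sensing molecules,other,,3;6
D-lactate,other,C[C@@H](O)C(O)=O,1
mycolactone,other,,2
pyruvate,other,CC(=O)C(O)=O,4
fumarate,other,OC(=O)/C=C/C(O)=O,5;8
malate,other,OC(CC(O)=O)C(O)=O,4
acetoin,other,CC(O)C(C)=O,8
"2,3-butanediol",other,CC(O)C(C)O,9
glycerol,other,OCC(O)CO,5
taurine,other,NCCS(O)(=O)=O,4;8
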