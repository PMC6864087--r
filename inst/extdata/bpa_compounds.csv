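# Benzylphenoxyacetamide (BPA) family compounds, transcribed from the IUPAC
# names given in the synthesis methods and running text. Compounds whose
# structures appear only in figure artwork and cannot be unambiguously named
# from the text are excluded: HR3, HR6-HR8, HR10-HR30, HR33, HR37, HR38,
# HR41-HR45, HR47, HR57.
# Region tags: region_a = halogen on the distal ring (Cl/F/H);
# region_b = linker (carbonyl/methylene/ether/reduced-ring);
# region_c = alpha substitution (gem-dimethyl/monomethyl/unsubstituted);
# region_d = amide (or ester/acid) moiety label. salt = counterion or none.
id,name,smiles,region_a,region_b,region_c,region_d,salt,synonyms
FF,isopropyl 2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanoate,CC(C)OC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,ester-isopropyl,none,fenofibrate
FFA,2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanoic acid,OC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,acid,none,fenofibric acid
AA,2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanamide,NC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,primary,none,
MA,2-(4-(4-chlorobenzoyl)phenoxy)-N-2-dimethylpropanamide,CNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,sec-N-methyl,none,
DMA,2-(4-(4-chlorobenzoyl)phenoxy)-N-N-2-trimethylpropanamide,CN(C)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-NN-dimethyl,none,
HR1,2-(4-(cyclohexylmethyl)phenoxy)-N-(2-hydroxyethyl)-N-2-dimethylpropanamide,OCCN(C)C(=O)C(C)(C)Oc1ccc(CC2CCCCC2)cc1,H,reduced-ring,gem-dimethyl,tert-N-methyl-N-hydroxyethyl,none,
HR2,2-(4-(4-chlorobenzyl)phenoxy)-N-(2-hydroxyethyl)-N-2-dimethylpropanamide,OCCN(C)C(=O)C(C)(C)Oc1ccc(Cc2ccc(Cl)cc2)cc1,Cl,methylene,gem-dimethyl,tert-N-methyl-N-hydroxyethyl,none,
HR4,2-(4-(4-chlorophenoxy)phenoxy)-N-(2-hydroxyethyl)-N-2-dimethylpropanamide,OCCN(C)C(=O)C(C)(C)Oc1ccc(Oc2ccc(Cl)cc2)cc1,Cl,ether,gem-dimethyl,tert-N-methyl-N-hydroxyethyl,none,
HR5,2-(4-(4-chlorophenoxy)phenoxy)-N-N-bis(2-hydroxyethyl)-2-methylpropanamide,OCCN(CCO)C(=O)C(C)(C)Oc1ccc(Oc2ccc(Cl)cc2)cc1,Cl,ether,gem-dimethyl,tert-NN-bis-hydroxyethyl,none,
HR9,2-(4-(4-fluorobenzoyl)phenoxy)-N-(2-hydroxyethyl)-N-2-dimethylpropanamide,OCCN(C)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(F)cc2)cc1,F,carbonyl,gem-dimethyl,tert-N-methyl-N-hydroxyethyl,none,fluoro-PP1
HR31,N-(4-aminobutyl)-2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanamide,NCCCCNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,sec-N-aminobutyl,none,
HR32,2-(4-(4-chlorobenzoyl)phenoxy)-N-(2-(diethylamino)ethyl)-2-methylpropanamide,CCN(CC)CCNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,sec-N-diethylaminoethyl,none,
HR34,(4-(4-chlorobenzoyl)phenoxy)-2-methyl-1-(4-methylpiperazin-1-yl)propan-1-one,CN1CCN(CC1)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-N-methylpiperazine,none,
HR35,4-(2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanoyl)-1-methylpiperazin-1-ium chloride,[Cl-].C[NH+]1CCN(CC1)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-N-methylpiperazine,chloride,
HR36,4-(2-(4-(4-chlorobenzoyl)phenoxy)-2-methylpropanoyl)-1-1-dimethylpiperazin-1-ium iodide,[I-].C[N+]1(C)CCN(CC1)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-NN-dimethylpiperazinium,iodide,
HR39,2-(4-(4-chlorobenzoyl)phenoxy)-N-(2-hydroxyethyl)-2-methylpropanamide,OCCNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,sec-N-hydroxyethyl,none,
PP1,2-(4-(4-chlorobenzoyl)phenoxy)-N-(2-hydroxyethyl)-N-2-dimethylpropanamide,OCCN(C)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-N-methyl-N-hydroxyethyl,none,HR40
HR46,2-(4-(4-chlorobenzoyl)phenoxy)-N-N-bis(2-hydroxyethyl)-2-methylpropanamide,OCCN(CCO)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1,Cl,carbonyl,gem-dimethyl,tert-NN-bis-hydroxyethyl,none,
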