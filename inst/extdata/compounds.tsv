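# Imidazo[1,2-a]pyridine library 4a-4o: scaffold = 3-hydroxy-5,5-dimethyl-
# cyclohex-2-enone linked to C3 of a 2-arylimidazo[1,2-a]pyridine.
# r1 = pyridine-ring substituent; r2 = 2-aryl substituent.
# logp = externally predicted octanol/water partition coefficient (data).
id	r1	r2	smiles	logp	name
4a	H	H	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccccc2)nc2ccccn12	3.56	3-hydroxy-5,5-dimethyl-2-(2-phenylimidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
4b	H	4-Cl	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(Cl)cc2)nc2ccccn12	4.12	2-(2-(4-chlorophenyl)imidazo[1,2-a]pyridin-3-yl)-3-hydroxy-5,5-dimethylcyclohex-2-enone
4c	H	2-OH	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccccc2O)nc2ccccn12	3.18	3-hydroxy-2-(2-(2-hydroxyphenyl)imidazo[1,2-a]pyridin-3-yl)-5,5-dimethylcyclohex-2-enone
4d	H	4-OMe	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(OC)cc2)nc2ccccn12	3.59	3-hydroxy-2-(2-(4-methoxyphenyl)imidazo[1,2-a]pyridin-3-yl)-5,5-dimethylcyclohex-2-enone
4e	H	4-Br	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(Br)cc2)nc2ccccn12	4.19	2-(2-(4-bromophenyl)imidazo[1,2-a]pyridin-3-yl)-3-hydroxy-5,5-dimethylcyclohex-2-enone
4f	H	3-NO2	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2cccc([N+](=O)[O-])c2)nc2ccccn12	2.85	3-hydroxy-5,5-dimethyl-2-(2-(3-nitrophenyl)imidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
4g	H	4-NO2	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc([N+](=O)[O-])cc2)nc2ccccn12	2.84	3-hydroxy-5,5-dimethyl-2-(2-(4-nitrophenyl)imidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
4h	4-CH3	H	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccccc2)nc2ccc(C)cn12	3.89	3-hydroxy-5,5-dimethyl-2-(2-phenyl-7-methylimidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
4i	4-CH3	4-Br	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(Br)cc2)nc2ccc(C)cn12	4.54	2-(2-(4-bromophenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)-3-hydroxy-5,5-dimethylcyclohex-2-enone
4j	4-CH3	4-OH	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(O)cc2)nc2ccc(C)cn12	3.49	3-hydroxy-2-(2-(4-hydroxyphenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)-5,5-dimethylcyclohex-2-enone
4k	4-CH3	3-NO2	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2cccc([N+](=O)[O-])c2)nc2ccc(C)cn12	3.20	3-hydroxy-5,5-dimethyl-2-(2-(3-nitrophenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
4l	4-CH3	2-OH	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccccc2O)nc2ccc(C)cn12	3.45	3-hydroxy-2-(2-(2-hydroxyphenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)-5,5-dimethylcyclohex-2-enone
4m	4-CH3	4-Cl	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(Cl)cc2)nc2ccc(C)cn12	4.45	2-(2-(4-chlorophenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)-3-hydroxy-5,5-dimethylcyclohex-2-enone
4n	4-CH3	4-OMe	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc(OC)cc2)nc2ccc(C)cn12	3.91	3-hydroxy-2-(2-(4-methoxyphenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)-5,5-dimethylcyclohex-2-enone
4o	4-CH3	4-NO2	OC1=C(C(=O)CC(C)(C)C1)c1c(-c2ccc([N+](=O)[O-])cc2)nc2ccc(C)cn12	3.21	3-hydroxy-5,5-dimethyl-2-(2-(4-nitrophenyl)-7-methylimidazo[1,2-a]pyridin-3-yl)cyclohex-2-enone
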