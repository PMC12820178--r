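metabolite_id	sub_pathway	super_pathway
M0001	SP21	Lipid
M0002	SP02	Amino Acid
M0003	SP16	Lipid
M0004	SP16	Lipid
M0005	SP09	Xenobiotics
M0006	SP20	Cofactors and Vitamins
M0007	SP06	Lipid
M0008	SP01	Lipid
M0009	SP18	Carbohydrate
M0010	SP01	Lipid
M0011	SP12	Amino Acid
M0012	SP15	Cofactors and Vitamins
M0013	SP01	Lipid
M0014	SP08	Carbohydrate
M0015	SP08	Carbohydrate
M0016	SP08	Carbohydrate
M0017	SP21	Lipid
M0018	SP03	Carbohydrate
M0019	SP02	Amino Acid
M0020	SP21	Lipid
M0021	SP02	Amino Acid
M0022	SP04	Xenobiotics
M0023	SP13	Carbohydrate
M0024	SP09	Xenobiotics
M0025	SP09	Xenobiotics
M0026	SP17	Amino Acid
M0027	SP23	Carbohydrate
M0028	SP15	Cofactors and Vitamins
M0029	SP10	Cofactors and Vitamins
M0030	SP12	Amino Acid
M0031	SP04	Xenobiotics
M0032	SP18	Carbohydrate
M0033	SP09	Xenobiotics
M0034	SP22	Amino Acid
M0035	SP08	Carbohydrate
M0036	SP15	Cofactors and Vitamins
M0037	SP22	Amino Acid
M0038	SP03	Carbohydrate
M0039	SP12	Amino Acid
M0040	SP22	Amino Acid
M0041	SP03	Carbohydrate
M0042	SP02	Amino Acid
M0043	SP04	Xenobiotics
M0044	SP16	Lipid
M0045	SP10	Cofactors and Vitamins
M0046	SP07	Amino Acid
M0047	SP06	Lipid
M0048	SP24	Xenobiotics
M0049	SP23	Carbohydrate
M0050	SP12	Amino Acid
M0051	SP16	Lipid
M0052	SP17	Amino Acid
M0053	SP02	Amino Acid
M0054	SP16	Lipid
M0055	SP16	Lipid
M0056	SP11	Lipid
M0057	SP09	Xenobiotics
M0058	SP19	Xenobiotics
M0059	SP21	Lipid
M0060	SP13	Carbohydrate
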