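sample_id	gestational_diabetes	preeclampsia	cesarean_section
S0001	0	0	0
S0002	0	0	0
S0003	0	0	0
S0004	0	0	0
S0005	0	0	0
S0006	0	0	1
S0007	0	0	0
S0008	0	0	0
S0009	0	0	0
S0010	0	0	0
S0011	0	0	0
S0012	0	0	0
S0013	0	0	0
S0014	0	0	0
S0015	0	0	0
S0016	0	0	1
S0017	0	0	0
S0018	0	0	0
S0019	0	0	1
S0020	0	0	0
S0021	0	0	0
S0022	0	0	1
S0023	0	0	0
S0024	0	0	0
S0025	0	0	0
S0026	0	0	0
S0027	0	0	0
S0028	0	0	0
S0029	0	0	0
S0030	0	0	0
S0031	0	0	0
S0032	0	1	1
S0033	0	0	0
S0034	1	0	0
S0035	0	0	1
S0036	0	0	0
S0037	0	0	0
S0038	0	0	0
S0039	0	0	0
S0040	0	1	0
S0041	0	0	1
S0042	0	0	0
S0043	0	0	0
S0044	0	0	0
S0045	0	0	0
S0046	0	0	0
S0047	1	0	0
S0048	0	0	0
S0049	0	0	0
S0050	0	0	0
S0051	0	0	0
S0052	0	0	1
S0053	0	0	1
S0054	0	0	0
S0055	0	0	0
S0056	0	0	0
S0057	0	0	1
S0058	0	0	0
S0059	0	0	0
S0060	0	0	0
S0061	0	0	1
S0062	0	1	0
S0063	0	0	1
S0064	0	0	0
S0065	0	0	0
S0066	0	0	1
S0067	0	0	1
S0068	0	0	1
S0069	0	0	0
S0070	0	0	1
S0071	0	0	0
S0072	0	0	0
S0073	0	0	0
S0074	0	0	0
S0075	0	0	0
S0076	0	0	0
S0077	0	0	0
S0078	0	0	0
S0079	0	0	0
S0080	0	0	1
S0081	0	0	0
S0082	0	0	0
S0083	0	0	0
S0084	0	0	0
S0085	0	0	0
S0086	0	0	0
S0087	0	0	0
S0088	0	0	1
S0089	0	0	0
S0090	0	0	0
S0091	0	0	0
S0092	0	0	0
S0093	0	0	1
S0094	0	0	0
S0095	0	0	0
S0096	0	0	0
S0097	0	0	0
S0098	0	0	0
S0099	1	0	0
S0100	0	0	0
S0101	0	0	0
S0102	0	0	0
S0103	0	0	0
S0104	0	0	0
S0105	0	0	0
S0106	0	0	0
S0107	0	0	1
S0108	0	0	0
S0109	0	0	1
S0110	1	0	1
S0111	0	0	0
S0112	0	0	0
S0113	0	0	0
S0114	0	0	0
S0115	0	0	0
S0116	0	0	1
S0117	0	1	1
S0118	0	0	0
S0119	0	0	0
S0120	0	0	0
S0121	0	0	0
S0122	0	0	0
S0123	0	0	0
S0124	0	0	1
S0125	0	0	1
S0126	0	0	0
S0127	0	0	0
S0128	0	0	0
S0129	0	0	0
S0130	0	0	0
S0131	0	0	1
S0132	0	0	0
S0133	0	0	0
S0134	1	0	0
S0135	0	0	0
S0136	0	0	0
S0137	0	0	0
S0138	0	0	1
S0139	0	0	0
S0140	0	0	0
S0141	0	0	0
S0142	0	0	0
S0143	0	0	0
S0144	0	0	1
S0145	0	0	0
S0146	0	0	0
S0147	0	0	0
S0148	0	1	0
S0149	0	0	0
S0150	0	0	1
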