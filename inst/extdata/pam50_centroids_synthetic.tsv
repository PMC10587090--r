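gene	Basal	HER2E	LumA	LumB	Normal
ACTR3B	0.816314	-0.019686	-0.611686	-0.103686	-0.495686
ANLN	0.400628	0.308628	-1.083372	0.580628	-0.961372
BAG1	-0.015058	0.092942	-0.249058	0.058942	-0.383058
BCL2	-1.436743	-0.828743	0.785257	0.593257	0.151257
BIRC5	0.412571	0.320571	-1.071429	0.636571	-0.949429
BLVRA	0.056885	0.164885	-0.177115	0.130885	-0.311115
CCNB1	0.440199	0.348199	-1.087801	0.620199	-0.921801
CCNE1	0.439513	0.347513	-1.044487	0.663513	-0.922487
CDC20	0.482827	0.346827	-1.045173	0.662827	-0.879173
CDC6	0.482142	0.390142	-1.001858	0.662142	-0.879858
CDCA1	0.481456	0.389456	-1.002544	0.705456	-0.836544
CDH3	1.16977	-0.26623	-0.70823	-0.80023	0.30777
CENPF	0.509084	0.417084	-0.974916	0.689084	-0.852916
CEP55	0.508398	0.416398	-0.975602	0.732398	-0.809602
CXXC5	-1.395788	-0.787788	0.826212	0.634212	0.192212
EGFR	1.193884	-0.198116	-0.640116	-0.732116	0.331884
ERBB2	-0.464659	1.443341	-0.398659	-0.040659	-0.382659
ESR1	-1.361345	-0.753345	0.860655	0.668655	0.226655
EXO1	0.532969	0.440969	-0.951031	0.756969	-0.829031
FGFR4	-0.173717	1.090283	-0.301717	0.056283	-0.135717
FOXA1	-1.326903	-0.718903	0.939097	0.703097	0.261097
FOXC1	1.230626	-0.161374	-0.603374	-0.695374	0.412626
GPR160	-1.026774	0.087226	0.345226	0.403226	-0.338774
GRB7	-0.14246	1.76554	-0.07646	0.23754	-0.10446
KIF2C	0.541854	0.449854	-0.942146	0.765854	-0.776146
KNTC2	0.585168	0.493168	-0.942832	0.765168	-0.776832
KRT14	1.283054	-0.108946	-0.550946	-0.642946	0.421054
KRT17	1.310225	-0.081775	-0.523775	-0.615775	0.492225
KRT5	1.381396	-0.010604	-0.496604	-0.588604	0.519396
MAPT	-1.298575	-0.690575	0.967425	0.775425	0.289425
MDM2	0.179739	0.243739	-0.098261	0.209739	-0.232261
MELK	0.594053	0.502053	-0.889947	0.774053	-0.767947
MIA	1.40551	0.01351	-0.42849	-0.52049	0.58751
MKI67	0.621681	0.485681	-0.906319	0.801681	-0.740319
MLPH	-1.251504	-0.643504	1.014496	0.778496	0.336496
MMP11	0.22031	0.32831	-0.01369	0.29431	-0.14769
MYBL2	0.633624	0.541624	-0.894376	0.813624	-0.728376
MYC	0.307938	0.415938	0.073938	0.381938	-0.104062
NAT1	-1.232748	-0.624748	1.033252	0.841252	0.399252
ORC6L	0.645566	0.553566	-0.882434	0.825566	-0.716434
PGR	-1.182619	-0.574619	1.083381	0.891381	0.405381
PHGDH	1.133195	0.297195	-0.294805	0.213195	-0.178805
PTTG1	0.657509	0.565509	-0.826491	0.837509	-0.704491
RRM2	0.656823	0.564823	-0.827177	0.880823	-0.661177
SFRP1	1.480137	0.044137	-0.397863	-0.489863	0.618137
SLC39A6	-1.135549	-0.527549	1.130451	0.894451	0.452451
TMEM45B	-0.751235	0.406765	0.664765	0.722765	-0.019235
TYMS	0.69708	0.60508	-0.83092	0.87708	-0.66492
UBE2C	0.696394	0.604394	-0.787606	0.920394	-0.665606
UBE2T	0.695708	0.603708	-0.788292	0.919708	-0.622292
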