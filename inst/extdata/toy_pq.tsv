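id	p	q	fold
var01	3.32586e-07	1.19836e-06	1
var02	1.75255e-11	4.23821e-06	2
var03	0.00035444	0.00159883	3
var04	0.003025	0.000320622	1
var05	0.00708287	0.00727169	2
var06	0.0941223	0.00358762	3
var07	6.54749e-05	0.0432583	1
var08	0.000463074	0.0806158	2
var09	0.208107	0.311355	3
var10	0.907746	0.000477126	1
var11	0.74171	0.000241602	2
var12	0.768325	0.414935	3
var13	0.52972	0.69018	1
var14	0.311008	0.722339	2
var15	0.607256	0.946508	3
var16	0.17073	0.193326	1
var17	0.908228	0.981413	2
var18	0.91792	0.529141	3
var19	0.0728081	0.599905	1
var20	0.44193	0.447099	2
var21	0.211405	0.637837	3
var22	0.814139	0.503122	1
var23	0.338219	0.51385	2
var24	0.536715	0.131565	3
var25	0.458465	0.67596	1
var26	0.399003	0.0479059	2
var27	0.394719	0.296162	3
var28	0.0999964	0.620095	1
var29	0.405752	0.130654	2
var30	0.12402	0.110575	3
var31	0.573544	0.471364	1
var32	0.527762	0.417438	2
var33	0.182213	0.082353	3
var34	0.0822681	0.0613199	1
var35	0.589234	0.0948901	2
var36	0.199197	0.0332872	3
var37	0.0891425	0.672205	1
var38	0.0698509	0.176038	2
var39	0.16754	0.0176643	3
var40	0.43777	0.73719	1
var41	0.0455985	0.498984	2
var42	0.455556	0.504162	3
var43	0.51192	0.975408	1
var44	0.625499	0.213937	2
var45	0.0371104	0.132947	3
var46	0.824933	0.70859	1
var47	0.31262	0.702629	2
var48	0.131402	0.840788	3
var49	0.783997	0.985741	1
var50	0.215199	0.385657	2
var51	0.434783	0.490662	3
var52	0.662805	0.51229	1
var53	0.906362	0.333339	2
var54	0.778785	0.524924	3
var55	0.205284	0.88999	1
var56	0.859787	0.197574	2
var57	0.692925	0.513096	3
var58	0.471289	0.414975	1
var59	0.282183	0.347567	2
var60	0.298101	0.380132	3
var61	0.123837	0.22761	1
var62	0.871456	0.250903	2
var63	0.928592	0.249499	3
var64	0.660292	0.967919	1
var65	0.716358	0.555469	2
var66	0.44105	0.721301	3
var67	0.525723	0.00415462	1
var68	0.66733	0.650023	2
var69	0.605666	0.616383	3
var70	0.0839993	0.820161	1
var71	0.413412	0.73273	2
var72	0.575607	0.07188	3
var73	0.366124	0.218958	1
var74	0.138409	0.258197	2
var75	0.0261056	0.358489	3
var76	0.524557	0.239789	1
var77	0.167648	0.336436	2
var78	0.0842107	0.236552	3
var79	0.354086	0.524751	1
var80	0.678162	0.211122	2
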