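snp_id	chrom	pos	risk_allele	other_allele	odds_ratio	risk_allele_freq
sim_rs001	6	7814171	G	T	1.2829790779622272	0.27695573233067994
sim_rs002	15	8218063	C	A	1.2719679239206017	0.28351030619814993
sim_rs003	2	12873915	C	T	1.0873280906351284	0.1429930726066232
sim_rs004	22	15338454	C	G	1.1736427497351543	0.4058631530962885
sim_rs005	18	19201451	G	C	1.1515874277800322	0.3813260673545301
sim_rs006	16	19773872	T	A	1.0590298067079857	0.11057945247739553
sim_rs007	15	20998267	T	C	1.0897157712141052	0.12244529509916902
sim_rs008	17	23704062	C	T	1.2006047748262063	0.18176593855023385
sim_rs009	17	24131492	T	C	1.0704697697772645	0.16434058034792542
sim_rs010	6	25224851	C	T	1.222404760553036	0.14085952499881388
sim_rs011	5	27473790	G	A	1.2592378418892622	0.3742178890854121
sim_rs012	20	27476574	C	G	1.1058372814557516	0.36521814074367287
sim_rs013	4	33008011	C	A	1.2102320499368944	0.41648302795365455
sim_rs014	8	34768400	A	C	1.228306840301957	0.19475489640608432
sim_rs015	19	39364703	G	T	1.1419666345580481	0.25380284506827594
sim_rs016	3	40897865	G	C	1.118361448997166	0.34654095405712726
sim_rs017	2	42593912	A	G	1.1149965787888505	0.2914733486250043
sim_rs018	17	43266931	G	T	1.1920477360952646	0.23430462311953307
sim_rs019	8	44857419	T	G	1.0537804502644577	0.40755456984043126
sim_rs020	9	46697587	G	C	1.2578504367382266	0.3853358050808311
sim_rs021	17	47296073	T	C	1.2341818827087991	0.30239117043092845
sim_rs022	9	49629484	C	G	1.1324454930843786	0.2385858502238989
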