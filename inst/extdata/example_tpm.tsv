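gene_id	tumour_001	tumour_002	tumour_003	tumour_004	tumour_005	tumour_006	tumour_007	tumour_008	cellline_01	cellline_02	cellline_03	cellline_04
g00001	3833.62832276257	12773.2077865666	6896.93922116616	3406.48128854204	8694.88404279911	3529.91261642772	3219.49915595574	13968.2623503661	997.705090099859	1758.97279090074	731.878981662114	1122.24869005089
g00002	41065.1290343468	37934.2531301781	21977.5637621147	21297.6541673556	42758.2008136858	28927.9845729072	37553.8010090099	37266.9062208329	48658.0876116601	41782.2231132819	36925.1406139557	42981.6640304297
g00003	216341.623881683	151296.075736772	177327.352975994	104899.103519491	149499.624863734	184612.41347997	197723.2731469	155011.160937241	289501.50044222	178577.524704094	181627.767718929	245888.850875721
g00004	2321.38689995127	2381.77030106605	2857.70806162287	2044.48655420721	2933.11829170984	2025.88320570025	2461.00059589327	2147.32869218224	3125.55682465192	3790.22089473986	3095.32229181024	3098.03879768141
g00005	189907.477314469	395272.848746409	328864.332410422	447386.591140899	303362.609555714	357098.845017742	327621.927511123	366680.279304247	81214.8163472485	103939.162185402	127705.466447767	126651.643144701
g00006	18743.241408966	25355.0845358869	26517.2094789274	25283.3548542645	50320.1053153422	24654.2458437078	25180.7943005457	38587.5987057754	31480.7110201635	45459.256466542	24922.6883412133	29220.1591814293
g00007	2572.51869891652	1729.54219271844	1814.53510373073	1142.67576878563	2251.23739939163	1128.40473462449	1352.60240360166	1466.05305050329	1486.55906330875	2610.30702316924	1633.86790010979	2412.99064230675
g00008	4587.81064601634	3756.21696148118	4897.09704975059	3396.67314828957	5386.45630295252	4420.84874699297	3839.11067054618	4760.20334027489	5916.5432368594	5954.9844604708	6070.3862957986	6028.59313884172
g00009	2200.27840194176	6181.30099291724	3871.86052848529	1375.70578846587	4206.46688233891	1441.42174343274	1217.50769719361	3053.06871630043	511.667076928207	293.277219719092	262.709239143533	377.784688034466
g00010	15299.5424037454	21905.5022993319	14551.0926195668	14205.3085336151	21708.4802843526	8882.09373198643	10579.3256675192	15808.050139899	88702.5056992879	70716.2139772901	58316.2390733716	85587.2664468341
g00011	648.252033983237	754.506880464774	585.708206862073	670.341246789823	490.455561217566	646.019532414926	655.205810916862	519.260886665001	928.227313390846	867.064402374375	553.561990013053	788.95606669277
g00012	214990.46420773	37064.2364426768	36288.4919738195	37538.0110811585	141485.585050975	157013.944179657	141617.893603759	59057.4516155162	47023.0658659507	74680.0611468357	235831.890844631	160190.480524328
g00013	6043.12670692751	5492.79987515575	7518.6635649247	4949.14625344331	7601.48712008229	4764.85346168554	4661.96415339793	6481.52600048779	9915.94781165023	8453.7138445415	5933.75228635452	8469.53580976285
g00014	15693.4319940954	21630.777876799	33172.1913420281	18969.8608559417	13721.8814066782	13717.5331900957	15015.9692966694	17982.4567200921	24066.9265086159	25412.2824074817	20698.9429360016	26908.616578931
g00015	32744.4011704849	54570.1766640911	92909.6311911771	104805.293750207	27511.0018339642	23447.2936200502	33724.7391058506	89259.9037443693	142370.822188507	174825.970627568	35564.1985426096	30206.2641825417
g00016	142043.101176716	124901.846843267	124548.453347399	124951.111973885	138684.309772388	95379.8474092048	110868.421640083	96199.507178237	110043.473228662	153421.672849456	183437.146657824	130847.690457847
g00017	4368.96883053823	16664.8812486625	14016.056779232	4013.29113262725	8553.82437588884	2564.47449010444	2992.35351277418	12828.7072986526	1014.67149098964	846.568641520697	574.085614163529	715.626010119667
g00018	81267.9148736917	72866.1788049776	95564.6819642876	73207.070318433	64223.7882010234	81087.3114499345	76204.7327305601	70441.3553677893	108566.51489149	97317.3901589476	71801.0619001836	93066.4137572193
g00019	4303.18621910864	5663.62171460896	4056.03662418091	5526.74725620696	4227.27075197893	4279.51191913404	2893.38858724439	5219.39203579705	4293.68075440981	9108.02835669479	4196.46632115391	5302.31132383615
g00020	1024.51577392587	1805.1709659696	1764.39379430844	931.091367391268	2379.21217378325	377.157054227016	616.489400455358	3261.52769477092	181.017533905649	185.104728970033	117.426003304041	134.865652691178
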