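protein	COAD_01	COAD_02	COAD_03	COAD_04	READ_01	READ_02	READ_03	READ_04
P00001	30.2431803785526	31.6288414820748	31.8698577998849	32.0921207428382	26.987693496457	33.5206571458748	27.7596169312664	26.7774870566488
P00002	24.808021254458	26.4993449265777	25.4878991887135	24.5939549830364	23.5294934805113	23.5652775439468	22.7362015206945	27.3204283903849
P00003	NA	21.7835242982269	22.8197473586505	22.5893373727441	22.4904555631819	NA	19.3854023549694	20.4299498345877
P00004	NA	22.8747866693808	19.5715016284085	23.7070407268327	NA	19.6267969171282	23.6252846246982	NA
P00005	24.879648083664	24.3205694069879	25.1746116742945	23.6777204709269	18.5410216458861	25.0219768696757	22.1014009341424	20.9440771987572
P00006	23.9222288793534	32.0928656158648	22.3490562537918	28.040669159441	32.1900855766055	29.4721168991337	28.3118199040706	27.6400010066789
P00007	23.0100163506591	26.861439693544	22.19789003502	NA	26.7568089248762	NA	NA	18.3800567588869
P00008	30.8156934327751	32.1563173583821	29.1968158574701	33.2636900489	29.6826996129711	27.3149950899795	28.1744888133699	32.5223915670107
P00009	26.040657145644	23.2143511977671	23.5251716102154	19.5248118588339	22.901108805322	14.7113919926458	20.9535303809438	16.3448988625847
P00010	22.7432593497353	22.1532833534167	26.1434691199801	26.7376345391828	24.839908870727	27.7873042212534	NA	16.7349230221164
P00011	20.7188401867778	19.5637427452843	21.4399190173554	24.7479330929023	21.7412486530828	NA	25.0535553597468	NA
P00012	20.0950959021615	NA	20.4318818931092	24.2189154749105	24.1378044736773	19.6247791771694	23.4748057875932	NA
P00013	26.3989692461781	22.1549859513649	28.7775440664625	31.5856567723949	31.2707752492712	27.3807632381588	25.8286912761235	26.4228286822699
P00014	19.9222829264425	17.5265209656045	NA	NA	NA	NA	24.1823709962662	19.4002256735849
P00015	29.6131588944001	21.1912157007124	28.2622662518958	26.2087493743724	25.7477924861349	21.2165398148253	24.4770975628741	22.0843926952827
P00016	22.2060568059415	NA	23.1992244380592	22.9525879309313	22.4218324590459	20.7167830684955	19.0268144586772	24.8876079290881
P00017	NA	25.5001739522631	27.0403019455669	26.0669811207666	26.1531282204428	24.6151947242382	24.9213273187608	25.574177143932
P00018	23.3837137476627	28.6651300148208	20.5122110520296	23.6544673362026	NA	22.3675836700646	13.3713526912252	NA
P00019	28.873088003252	31.1407609088369	28.2605382456635	24.3825634180273	NA	37.4372032820198	33.4985742227762	27.0070951589489
P00020	23.1358178949286	23.1824851579176	24.9631138091481	NA	25.0568609821764	26.5435765172202	21.1530769650015	NA
P00021	28.4712288374115	27.4801816377294	29.2862036079477	27.8790517345925	29.8507317349495	26.3214380458168	26.4371940319747	34.4598219153718
P00022	28.5862080364395	NA	24.9704047028628	23.6360567227286	NA	24.9344470564433	22.0910931135046	26.4089372397039
P00023	32.4531908122272	27.2439805864614	26.9124658211344	31.6240207288016	32.082307734541	34.1458265515873	35.1965611328074	33.1204756275076
P00024	30.5367062132278	28.1034748734545	33.7990394675284	28.8402648435625	29.8461092781092	25.4489649092746	24.537849156196	30.5031682673657
P00025	24.701709000695	28.7427787947053	25.7802914058281	26.9472843602989	32.2946995467549	27.8720155137191	29.8326262502977	27.8454497107431
P00026	21.4416057300158	19.9049666546749	23.3787482696894	21.8553181815462	23.9231425722653	21.611864445351	NA	NA
P00027	26.58692945426	22.864729878651	28.1445118108294	26.9197070505868	26.5510154327895	23.6022595869455	26.2679905360345	24.5504871736463
P00028	23.1336685624246	26.0605484881019	25.5036878056043	22.7439579623233	23.7267825618721	27.3303815183991	24.0507401592589	27.5411448853853
P00029	29.8995020872048	33.7639450613039	25.8574600933552	28.8287893055509	35.1436044713256	NA	28.7052186244157	31.7022946335003
P00030	23.9699234506454	22.2121175891892	27.0520320966214	26.0195388659766	28.7063751930507	NA	23.9613549380069	24.3180056756842
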