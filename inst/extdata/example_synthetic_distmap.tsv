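#complex_id	example_synthetic
#peptide	IDIRINWYIV
#cdrb	HGRSWKVTMTMTKGYFMCYFTSRKPQ
16.7051627375185	26.3364451313391	18.389652675949	22.6168129518628	19.8811261858791	18.4210914717987	34.8509696880355	33.2731471452862	33.9580117203295	12.3288331413642	33.4574548620731	21.1021262025461	32.0718853557482	20.8287596255541	25.6501393960789	33.6341159325093	7.78002076409757	4.04057923913933	4.6106746639125	25.2121769981459	32.4819459291175	32.396928826347	21.0067896358669	21.1067433040589	13.8872694512829	18.241092313081
34.6104591740295	26.1406695963815	12.4292369903997	22.4518673531711	34.0158737143502	17.9639563402161	13.6131637990475	33.3029585126787	30.3219376076013	19.4872816801071	31.0997023591772	14.1942608030513	35.0212653288618	25.8200183650479	20.9384438144043	15.5035066697747	8.63184956926852	7.61362787312828	4.03956216387451	35.833509282209	36.0937228975818	25.3454202534631	34.6931074457243	23.6627447549254	32.5764540806413	19.1463036695495
22.7783858384937	26.9529898967594	15.6114836409688	16.7681380007416	16.8445417815819	36.5588253643364	34.4792189868167	37.2913036663085	22.5869231252	24.1960188485682	17.8556621810421	16.2061535771936	34.9807739499956	21.4547682804987	31.033976203762	36.8699058620259	6.78458326589316	8.62810209719464	4.11860086000524	21.0166284609586	21.5958873992786	28.2929754471406	22.9154595425352	26.1592526305467	30.0180810475722	30.2078117635101
21.1765608806163	27.6029841993004	14.6146939983591	24.6926050614566	27.980930509977	39.8102149721235	14.9228593902662	39.055918010883	12.2398750884458	35.2250786526129	31.9344253074378	16.2679019486532	17.5984474504367	18.2380078434944	36.1241099219769	20.6617093365639	7.0967371724546	8.62790568708442	5.967186256079	27.628405302763	25.8018210101873	17.7974132299423	28.6902894172817	29.2854198152199	13.8859357805923	29.2834358029068
28.8588188933209	36.3017456540838	18.6327802091837	19.2355908928439	23.7399229714647	35.6389165557921	33.4649685220793	26.4271854385734	38.7492275033146	36.3864330779761	28.9483491936699	37.5758608300239	28.8317937394604	35.2467107241973	35.7196132028475	30.179642864503	8.66128500178456	4.94864817569032	4.80550344195217	31.7600086871535	35.9078918388113	12.8082481892779	21.5074146855623	28.3916028114036	31.5292212879285	19.0936343036592
28.9230335131288	35.2318434128538	34.1521274652332	21.415446665138	19.4934206241742	37.4922233782709	20.5346958581358	27.3854588679969	35.4812521403655	19.0299308653921	21.5356577411294	31.663081173785	24.0354080544785	27.0779099501669	19.4836613470688	19.3470428111032	7.35571429459378	5.77291687461548	5.84671059018001	22.9406470740214	22.8430840112269	39.251311856322	32.1055125752464	37.178458862938	21.7792929420248	26.526155885309
15.4897364387289	15.1205762950704	28.7924838392064	36.9083249708638	13.338664370589	25.1955525055528	33.5400477852672	16.5841571139172	17.9758982518688	21.0820309547707	13.1527689862996	34.9753530174494	29.8519132900983	14.7635410586372	28.951295344159	16.5237749442458	4.25661789346486	4.47850885544904	6.1985892392695	35.0786469643936	32.3422107966617	18.9281867742538	38.5230349684134	28.0972762592137	20.7940691998228	13.1850400762632
20.2488258788362	31.7032740488648	37.484135906212	17.6544963670895	14.8978055100888	18.2837154241279	27.1383603373542	16.6087147025391	25.8519795751199	20.5746587337926	23.2490702634677	30.6357665397227	23.7606721464545	15.0685239899904	35.2667132876813	14.9541949732229	4.88219112483785	4.38136277697049	8.98549615149386	37.3828798532486	31.1554076066241	15.3509752834216	14.2800780730322	20.7713332679123	39.5048728557304	25.1838949248195
28.1730777323246	37.1296714022756	27.6918875100091	28.2172091975808	20.7928807586432	15.578810384497	22.146374902688	34.0173177691177	29.8148391759023	17.1598969828337	14.2136700749397	18.0531831886619	36.6363610904664	28.0679408693686	28.5665770042688	24.2550509907305	6.75432295980863	4.95094640157185	8.09624500316568	23.6792772021145	35.6749228937551	31.1761359069496	18.5922534242272	25.440056710504	33.0032550133765	36.5342906583101
29.6674196831882	19.8325115051121	33.1597335366532	17.8136968370527	34.4179497417063	19.8311383472756	14.5915936529636	33.0311757503077	37.7905590068549	31.0393671868369	20.7514742128551	24.9657472781837	20.9803848545998	27.063584565185	17.5675111198798	13.0785808926448	5.00555162294768	5.32436152431183	7.41661611339077	19.8156962394714	12.9184372294694	32.560292461887	22.1513254446909	28.6773984124884	31.7360013499856	38.5949491318315
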