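	drug_001	drug_002	drug_003	drug_004	drug_005	drug_006	drug_007	drug_008	drug_009	drug_010	drug_011	drug_012	drug_013	drug_014
drug_001	1	1	0.969638127391498	1	0.955103641382487	1	1	0	0	0.00814973903056133	0.0033813801144788	0	0	0
drug_002	1	1	1	0.982970297088138	1	1	0.983097366155316	0.0129793638196767	0.0190783501638624	0	0.029930630716368	0.0114890400156268	0	0
drug_003	0.969638127391498	1	1	1	1	0.946129094608178	1	0	0	0.0682667853550435	0.0542411307987455	0	0.0142487303317009	0
drug_004	1	0.982970297088138	1	1	0.945037183562244	0.996463084564849	1	0.0242319581544815	0.0220326339758694	0.0333577635331437	4.71336239147024e-05	0	0	0
drug_005	0.955103641382487	1	1	0.945037183562244	1	0.952630367763729	0.978371419009711	0	0.0249602985847645	0	0	0.0638620196121218	0.00621382391563804	0
drug_006	1	1	0.946129094608178	0.996463084564849	0.952630367763729	1	1	0	0.0387899750114331	0.0200198677448276	0.000779768575127807	0.0098249269565988	0.0171982777767701	0.0656024621223111
drug_007	1	0.983097366155316	1	1	0.978371419009711	1	1	0.0153793086025241	0	0	0	0	0.0384775444528213	0
drug_008	0	0.0129793638196767	0	0.0242319581544815	0	0	0.0153793086025241	1	0.966063880233786	1	0.973216893673856	0.95900385425297	0.983962766927787	0.960877566095791
drug_009	0	0.0190783501638624	0	0.0220326339758694	0.0249602985847645	0.0387899750114331	0	0.966063880233786	1	0.965349470848123	0.984015532430889	0.986032132038984	0.977212251003689	0.989997000028001
drug_010	0.00814973903056133	0	0.0682667853550435	0.0333577635331437	0	0.0200198677448276	0	1	0.965349470848123	1	0.979995311250427	0.994895193324708	1	1
drug_011	0.0033813801144788	0.029930630716368	0.0542411307987455	4.71336239147024e-05	0	0.000779768575127807	0	0.973216893673856	0.984015532430889	0.979995311250427	1	0.983702349321667	1	0.989575284471085
drug_012	0	0.0114890400156268	0	0	0.0638620196121218	0.0098249269565988	0	0.95900385425297	0.986032132038984	0.994895193324708	0.983702349321667	1	0.986345039770761	0.964273594789893
drug_013	0	0	0.0142487303317009	0	0.00621382391563804	0.0171982777767701	0.0384775444528213	0.983962766927787	0.977212251003689	1	1	0.986345039770761	1	1
drug_014	0	0	0	0	0	0.0656024621223111	0	0.960877566095791	0.989997000028001	1	0.989575284471085	0.964273594789893	1	1
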