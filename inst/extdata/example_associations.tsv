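microbe	drug
microbe_001	drug_002
microbe_001	drug_005
microbe_001	drug_006
microbe_001	drug_008
microbe_002	drug_003
microbe_002	drug_005
microbe_002	drug_006
microbe_002	drug_010
microbe_003	drug_001
microbe_003	drug_004
microbe_003	drug_005
microbe_003	drug_006
microbe_004	drug_002
microbe_004	drug_007
microbe_005	drug_002
microbe_005	drug_003
microbe_005	drug_004
microbe_005	drug_005
microbe_005	drug_006
microbe_006	drug_009
microbe_006	drug_012
microbe_006	drug_013
microbe_006	drug_014
microbe_007	drug_004
microbe_007	drug_008
microbe_007	drug_009
microbe_007	drug_010
microbe_007	drug_012
microbe_008	drug_008
microbe_008	drug_009
microbe_008	drug_010
microbe_008	drug_012
microbe_008	drug_014
microbe_009	drug_008
microbe_009	drug_009
microbe_009	drug_011
microbe_009	drug_013
microbe_010	drug_008
microbe_010	drug_009
microbe_010	drug_011
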