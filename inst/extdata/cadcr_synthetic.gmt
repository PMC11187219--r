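cadcr_synthetic	synthetic CADCR gene identifiers used by the bundled generators	CRG001	CRG002	CRG003	CRG004	CRG005	CRG006	CRG007	CRG008	CRG009	CRG010	CRG011	CRG012	CRG013	CRG014	CRG015	CRG016	CRG017	CRG018	CRG019	CRG020	CRG021	CRG022	CRG023	CRG024	CRG025	CRG026	CRG027	CRG028	CRG029	CRG030	CRG031	CRG032	CRG033	CRG034	CRG035	CRG036	CRG037	CRG038	CRG039	CRG040	CRG041	CRG042	CRG043	CRG044	CRG045	CRG046	CRG047	CRG048	CRG049	CRG050
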