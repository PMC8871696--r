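gene_id	gene_set
STEM_SIG_001	stem_signature
STEM_SIG_002	stem_signature
STEM_SIG_003	stem_signature
STEM_SIG_004	stem_signature
STEM_SIG_005	stem_signature
STEM_SIG_006	stem_signature
STEM_SIG_007	stem_signature
STEM_SIG_008	stem_signature
STEM_SIG_009	stem_signature
STEM_SIG_010	stem_signature
STEM_SIG_011	stem_signature
STEM_SIG_012	stem_signature
STEM_SIG_013	stem_signature
STEM_SIG_014	stem_signature
STEM_SIG_015	stem_signature
STEM_SIG_016	stem_signature
STEM_SIG_017	stem_signature
STEM_SIG_018	stem_signature
STEM_SIG_019	stem_signature
STEM_SIG_020	stem_signature
STEM_SIG_021	stem_signature
STEM_SIG_022	stem_signature
STEM_SIG_023	stem_signature
STEM_SIG_024	stem_signature
STEM_SIG_025	stem_signature
STEM_SIG_026	stem_signature
STEM_SIG_027	stem_signature
STEM_SIG_028	stem_signature
STEM_SIG_029	stem_signature
STEM_SIG_030	stem_signature
STEM_SIG_031	stem_signature
STEM_SIG_032	stem_signature
STEM_SIG_033	stem_signature
STEM_SIG_034	stem_signature
STEM_SIG_035	stem_signature
STEM_SIG_036	stem_signature
STEM_SIG_037	stem_signature
STEM_SIG_038	stem_signature
STEM_SIG_039	stem_signature
STEM_SIG_040	stem_signature
STEM_SIG_041	stem_signature
STEM_SIG_042	stem_signature
STEM_SIG_043	stem_signature
STEM_SIG_044	stem_signature
STEM_SIG_045	stem_signature
STEM_SIG_046	stem_signature
STEM_SIG_047	stem_signature
STEM_SIG_048	stem_signature
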